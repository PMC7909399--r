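# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific random seed from a master seed
#'
#' Deterministically maps a master seed and a stage label (or integer offset)
#' to a new seed, so that independent analysis stages consume independent
#' random streams while the whole run stays reproducible from one integer.
#'
#' @param master integer master seed.
#' @param offset integer offset or character stage label.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1)
  if (is.character(offset)) {
    offset <- sum(utf8ToInt(offset) * seq_along(utf8ToInt(offset)))
  }
  # linear congruential mixing; kept well below .Machine$integer.max
  x <- (abs(master) %% 2147483647) + 1
  y <- (abs(offset) %% 2147483647) + 1
  as.integer((x * 48271 + y * 16807) %% 2147483629 + 1)
}

# Evaluate `expr` with a locally-set RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Indices of the strict upper triangle of an n x n matrix, column-major.
upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)))

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; input order is
#' preserved.  Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, entrywise `>= p` and `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Compact letter display from a symmetric matrix of pairwise p-values.
# Groups not significantly different (p >= alpha) share a letter.
# Insert-and-absorb algorithm over the significance graph.
compact_letters <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  labs <- rownames(pmat) %||% as.character(seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      # significant pair: split every set containing both
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets fully contained in another
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  # order letters by the smallest group index they contain
  sets <- sets[order(vapply(sets, min, 1L))]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
           collapse = "")
  }, character(1))
  names(out) <- labs
  out
}

# Permutation p-value convention used throughout: never exactly zero.
perm_pval <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}
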