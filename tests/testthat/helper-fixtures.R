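# Small in-code fixtures shared across tests.

toy_cm <- function() {
  counts <- rbind(S1 = c(6, 2, 0, 1, 3),
                  S2 = c(2, 2, 5, 0, 1),
                  S3 = c(0, 4, 4, 2, 0))
  colnames(counts) <- paste0("OTU", 1:5)
  tax <- c(OTU1 = "Bacteria;Proteobacteria;Gamma",
           OTU2 = "Bacteria;Actinobacteria;Acidimicrobiia",
           OTU3 = "Bacteria;Cyanobacteria;Chloroplast",
           OTU4 = "Bacteria;Bacteroidetes;Flavobacteriia",
           OTU5 = "Bacteria;Cyanobacteria;Oxyphotobacteria")
  community_matrix(counts, taxonomy = tax)
}

# Block-structured dissimilarity: within-group < between-group everywhere.
separated_dist <- function(n_per = 4, k = 2, within = 0.2, between = 0.8) {
  n <- n_per * k
  g <- rep(seq_len(k), each = n_per)
  m <- matrix(between, n, n)
  for (lev in seq_len(k)) m[g == lev, g == lev] <- within
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  list(d = dist_matrix(m, "dissimilarity"), groups = g)
}

small_sim <- function(nu, seed, n_species = 300, reads = 2000) {
  cfg <- sim_config(n_species = n_species, reads_per_sample = reads,
                    nu = nu, seed = seed)
  md <- simulate_metadata(cfg)
  sim <- simulate_communities(cfg, md)
  list(cfg = cfg, md = md, cm = sim$community, truth = sim$truth)
}

# Haversine great-circle distance in km (independent oracle for the
# equirectangular projection).
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
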