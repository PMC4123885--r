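# in-code fixtures used across test files

# a tiny hand-written specimen table: 3 specimens, one with 3 fields,
# one with a single field, one morphometrics-only
tiny_specimen_df <- function() {
  data.frame(
    specimen_id = c("A1", "A1", "A1", "B1", "C1"),
    species = c("sp_a", "sp_a", "sp_a", "sp_b", "sp_c"),
    order = "testorder",
    lineage = c("eutherian", "eutherian", "eutherian", "metatherian",
                "eutherian"),
    guild = c("grazer", "grazer", "grazer", "carnivore", "browser"),
    body_mass_g = c(1e5, 1e5, 1e5, 2e4, 5e4),
    length_mm = c(10, 10, 10, 8, 12),
    width_mm = c(8, 8, 8, 6, 9),
    crest_mm = c(25, 25, 25, 5, 33),
    Sf = c(10, 14, 12, 6, NA),
    Sc = c(5, 7, 6, 3, NA),
    Ps = c(2, 4, 3, 9, NA),
    Pl = c(1, 1, 1, 4, NA),
    stringsAsFactors = FALSE)
}

tiny_set <- function() specimen_set(tiny_specimen_df(), provenance = "test")

# well-separated gaussian clusters for discriminant tests
separated_clusters <- function(n_per = 10, gap = 10, p = 2, seed = 1) {
  set.seed(seed)
  g <- 3
  x <- do.call(rbind, lapply(seq_len(g), function(k) {
    matrix(stats::rnorm(n_per * p, mean = k * gap), n_per, p)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, groups = rep(letters[seq_len(g)], each = n_per))
}

# a synthetic config with guild distributions so far apart that every
# stage of the workflow separates perfectly
separable_config <- function(seed = 1) {
  guilds <- list(
    grazer = guild_params(log(2e5), 0.1, 3.0, 0.02,
                          c(Sf = 40, Sc = 30, Ps = 4, Pl = 1)),
    browser = guild_params(log(5e4), 0.1, 3.0, 0.02,
                           c(Sf = 40, Sc = 2, Ps = 30, Pl = 10)),
    hard_object = guild_params(log(3e3), 0.1, 3.0, 0.02,
                               c(Sf = 2, Sc = 2, Ps = 80, Pl = 40)),
    insectivore = guild_params(log(50), 0.1, 3.0, 0.02,
                               c(Sf = 30, Sc = 30, Ps = 30, Pl = 30)),
    carnivore = guild_params(log(3e4), 0.1, 0.5, 0.02,
                             c(Sf = 10, Sc = 10, Ps = 10, Pl = 10)))
  synthetic_config(guilds, n_species = 3, individuals_per_species = 3,
                   measurements_per_tooth = 2, seed = seed)
}
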