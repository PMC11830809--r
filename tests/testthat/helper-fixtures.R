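# Shared fixture builders: small traces and reactor bundles constructed in
# code, no stored data files.

flat_trace <- function(current_A = 1e-3, duration_s = 6 * 86400,
                       dt_s = 3600, area_cm2 = 2.25,
                       id = "flat") {
  t <- seq(0, duration_s, by = dt_s)
  current_trace(id, t, rep(-abs(current_A), length(t)), area_cm2)
}

step_trace <- function(baseline_A = 1e-4, plateau_A = 6e-4,
                       step_at_s = 86400, duration_s = 6 * 86400,
                       dt_s = 3600, area_cm2 = 2.25, id = "step") {
  t <- seq(0, duration_s, by = dt_s)
  i <- ifelse(t < step_at_s, baseline_A, plateau_A)
  current_trace(id, t, -i, area_cm2)
}

toy_amplicon <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- cbind(s1 = c(60000, 30000, 10000),
                    s2 = c(100000, 80000, 20000),
                    s3 = c(300, 150, 50))
    rownames(counts) <- c("ASV_a", "ASV_b", "ASV_c")
  }
  tax <- tibble::tibble(
    asv_id = rownames(counts),
    domain = "Bacteria",
    phylum = c("Firmicutes", "Firmicutes", "Proteobacteria"),
    class = c("Bacilli", "Bacilli", "Gammaproteobacteria"),
    order = c("Bacillales", "Bacillales", "Pseudomonadales"),
    family = c("Bacillaceae", "Bacillaceae", NA),
    genus = c("Bacillus", "Bacillus", NA))
  amplicon_table(counts, tax)
}

toy_bundle <- function(seed = 11, label = "electrotroph",
                       noise_scale = 0) {
  ds <- generate_experiment(label, master_seed = seed,
                            noise_scale = noise_scale)
  ds$reactors[[1]]
}
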