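# Shared builders for small in-memory panels.

# A trait table with all 14 canonical columns filled from a seeded uniform
# draw over each trait's plausible range; small and fast for unit tests.
random_trait_table <- function(n, seed = 1L) {
  set.seed(seed)
  m <- default_synthetic_spec()$marginals
  x <- sapply(seq_len(14), function(j) runif(n, m$min[j], m$max[j]))
  colnames(x) <- m$trait
  trait_table(data.frame(genotype_id = sprintf("G%03d", seq_len(n)),
                         as.data.frame(x, check.names = FALSE),
                         check.names = FALSE))
}

# Long-format raw records for one genotype x treatment x replicate with
# exact growth series (helper for assemble_trait_table hand checks).
raw_block <- function(g, trt, rep_, gr, nil, ler, h2 = 10, l2 = 5,
                      leaves1 = 4, sf = 4, sdry = 3.4, rf = 2, rdry = 1.7,
                      sen = 5, snc = 120, rnc = 45, skc = 70, rkc = 26) {
  rows <- rbind(
    data.frame(measure = "height_cm", das = c(2, 7, 17),
               value = c(h2, h2 + 5 * gr, h2 + 15 * gr)),
    data.frame(measure = "leaf_count", das = c(1, 17),
               value = c(leaves1, leaves1 + nil)),
    data.frame(measure = "leaf_length_cm", das = c(2, 7, 12),
               value = c(l2, l2 + 5 * ler, l2 + 10 * ler)),
    data.frame(measure = c("shoot_fresh_g", "shoot_dry_g", "root_fresh_g",
                           "root_dry_g"), das = NA,
               value = c(sf, sdry, rf, rdry)))
  if (trt == "stress")
    rows <- rbind(rows, data.frame(
      measure = c("senescence_score", "shoot_na_mg_g", "root_na_mg_g",
                  "shoot_k_mg_g", "root_k_mg_g"),
      das = NA, value = c(sen, snc, rnc, skc, rkc)))
  data.frame(genotype_id = g, treatment = trt, replicate = rep_, rows)
}
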