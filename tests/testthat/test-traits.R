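test_that("growth rates follow the stated interval arithmetic", {
  gr <- derive_growth_rates(heights = c(`2` = 10, `7` = 12, `17` = 20))$GR
  expect_equal(gr, mean(c(0.4, 2 / 3)), tolerance = 1e-12)
  expect_equal(derive_growth_rates(
    heights = c(`2` = 10, `7` = 10, `17` = 10))$GR, 0)
  expect_equal(derive_growth_rates(
    leaf_lengths = c(`2` = 5, `7` = 10, `12` = 15))$LER, 1)
  expect_equal(derive_growth_rates(
    leaf_counts = c(`1` = 3, `17` = 7))$NIL, 4)
  err <- tryCatch(derive_growth_rates(heights = c(`2` = 10, `7` = 12)),
                  error = identity)
  expect_match(conditionMessage(err), "GR")
  expect_match(conditionMessage(err), "17")
})

test_that("STI and SII are complementary ratios", {
  expect_equal(compute_sti_sii(0.4, 0.4), list(STI = 1, SII = 0))
  expect_equal(compute_sti_sii(0, 2), list(STI = 0, SII = 1))
  expect_equal(compute_sti_sii(0.2, 0.4), list(STI = 0.5, SII = 0.5))
  # STI + SII = 1 exactly for arbitrary inputs
  set.seed(1)
  s <- runif(50, 0, 3); c_ <- runif(50, 0.1, 3)
  r <- compute_sti_sii(s, c_)
  expect_identical(r$STI + r$SII, rep(1, 50))
  expect_error(compute_sti_sii(1, 0), "control")
})

test_that("water content uses the fresh-mass basis by default", {
  expect_equal(compute_water_content(10, 10), 0)
  expect_equal(compute_water_content(10, 0), 100)
  expect_equal(compute_water_content(8, 2), 75)
  expect_equal(compute_water_content(8, 2, basis = "dry"), 300)
  expect_error(compute_water_content(2, 8), "invalid")
})

test_that("assemble_trait_table matches cell-by-cell brute-force recomputation", {
  # 2 genotypes x 2 treatments x 3 replicates with distinct replicate values
  blocks <- list()
  truth <- list()
  for (g in c("A", "B")) {
    base <- if (g == "A") 0.3 else 0.5
    for (trt in c("control", "stress")) {
      f <- if (trt == "control") 1 else 0.6
      for (r in 1:3) {
        blocks[[length(blocks) + 1L]] <- raw_block(
          g, trt, r, gr = base * f + 0.01 * r, nil = 2 * f + 0.1 * r,
          ler = 1.2 * f + 0.05 * r, sen = 4 + r, snc = 100 + 10 * r,
          rnc = 40 + r, skc = 60 + r, rkc = 20 + r,
          sf = 4 + r, sdry = 3 + 0.5 * r, rf = 2 + r, rdry = 1.5 + 0.5 * r)
      }
    }
  }
  records <- do.call(rbind, blocks)
  tab <- assemble_trait_table(records)
  # independent recomputation: mean derived value per arm, then ratio
  for (g in c("A", "B")) {
    base <- if (g == "A") 0.3 else 0.5
    gr_ck <- mean(base + 0.01 * 1:3)
    gr_s <- mean(base * 0.6 + 0.01 * 1:3)
    row <- as.data.frame(tab)[tab$genotype_id == g, ]
    expect_equal(row$RGR, gr_s / gr_ck, tolerance = 1e-12)
    expect_equal(row$RNIL, mean(2 * 0.6 + 0.1 * 1:3) / mean(2 + 0.1 * 1:3),
                 tolerance = 1e-12)
    expect_equal(row$RLER,
                 mean(1.2 * 0.6 + 0.05 * 1:3) / mean(1.2 + 0.05 * 1:3),
                 tolerance = 1e-12)
    expect_equal(row$Sen, mean(4 + 1:3))
    expect_equal(row$SNC, mean(100 + 10 * 1:3))
    expect_equal(row$SWC,
                 mean((4 + 1:3 - (3 + 0.5 * 1:3)) / (4 + 1:3)) * 100,
                 tolerance = 1e-12)
    expect_equal(row[["SN/RN"]], row$SNC / row$RNC, tolerance = 1e-12)
    expect_equal(row[["SK/N"]] * row$SNC, row$SKC, tolerance = 1e-9)
    expect_equal(row[["RK/N"]] * row$RNC, row$RKC, tolerance = 1e-9)
  }
})

test_that("stress identical to control gives unit stress indices", {
  blocks <- list()
  for (trt in c("control", "stress")) for (r in 1:2)
    blocks[[length(blocks) + 1L]] <- raw_block("A", trt, r,
                                               gr = 0.4, nil = 2, ler = 1.1)
  tab <- assemble_trait_table(do.call(rbind, blocks))
  expect_equal(tab$RGR, 1); expect_equal(tab$RNIL, 1)
  expect_equal(tab$RLER, 1)
})

test_that("a genotype missing a treatment arm is excluded and reported", {
  blocks <- list(raw_block("A", "control", 1, 0.4, 2, 1.1),
                 raw_block("A", "stress", 1, 0.2, 1, 0.6),
                 raw_block("B", "control", 1, 0.4, 2, 1.1))
  expect_warning(tab <- assemble_trait_table(do.call(rbind, blocks)),
                 "excluded")
  expect_equal(tab$genotype_id, "A")
  expect_equal(nrow(attr(tab, "exclusions")), 1L)
  expect_equal(attr(tab, "exclusions")$genotype_id, "B")
})

test_that("assembly is permutation-equivariant in genotype order", {
  blocks <- list()
  for (g in c("A", "B", "C")) for (trt in c("control", "stress"))
    blocks[[length(blocks) + 1L]] <- raw_block(
      g, trt, 1, gr = 0.3 + 0.1 * match(g, c("A", "B", "C")) *
        (if (trt == "stress") 0.5 else 1), nil = 2, ler = 1)
  records <- do.call(rbind, blocks)
  t1 <- assemble_trait_table(records)
  t2 <- assemble_trait_table(records[rev(seq_len(nrow(records))), ])
  m1 <- trait_values(t1); m2 <- trait_values(t2)
  expect_equal(m1[sort(rownames(m1)), ], m2[sort(rownames(m2)), ],
               tolerance = 1e-12)
})

test_that("trait table CSV round-trips and validates its schema", {
  tab <- random_trait_table(5, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tab, path, provenance = "unit test")
  back <- load_trait_table(path)
  expect_equal(trait_values(back), trait_values(tab), tolerance = 1e-12)

  # extra column preserved but ignored
  df <- as.data.frame(tab)
  df$notes <- "x"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  back2 <- load_trait_table(path2)
  expect_equal(trait_values(back2), trait_values(tab), tolerance = 1e-12)

  # missing trait column is a named schema error
  df$Sen <- NULL
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path3, row.names = FALSE)
  expect_error(load_trait_table(path3), "Sen")
})

test_that("direction map default and YAML override behave", {
  dirs <- default_trait_directions()
  expect_setequal(names(dirs)[dirs == "negative"],
                  c("Sen", "SNC", "RNC", "SN/RN", "SKC", "RKC"))
  expect_equal(sum(dirs == "positive"), 8L)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(SKC = "positive"), path)
  over <- load_trait_directions(path)
  expect_equal(unname(over[["SKC"]]), "positive")
  expect_equal(unname(over[["Sen"]]), "negative")
})
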