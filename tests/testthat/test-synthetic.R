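test_that("expression generator is deterministic and exact in the zero-noise limit", {
  a <- gen_expression_dataset(100, seed = 7)
  b <- gen_expression_dataset(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$fpkm,
                         gen_expression_dataset(100, seed = 8)$fpkm))

  ds <- gen_expression_dataset(500,
                               effects = list(effect_spec("G1", 4, "2p22")),
                               background_sd = 0, seed = 7)
  expect_equal(ds$fpkm["G1", "BEC40W"] / ds$fpkm["G1", "BEC20W"], 4)
  # non-contrast samples keep the baseline
  expect_equal(ds$fpkm["G1", "BEC0W"], ds$fpkm["G1", "BEC20W"])
  # background gene ratios are exactly 1 without noise
  bg <- setdiff(rownames(ds$fpkm), "G1")
  pos <- bg[ds$fpkm[bg, 1] > 0]
  expect_equal(ds$fpkm[pos, "BEC40W"] / ds$fpkm[pos, "BEC20W"],
               setNames(rep(1, length(pos)), pos))
  # some genes not expressed at all, in every sample
  zero <- bg[ds$fpkm[bg, 1] == 0]
  expect_gt(length(zero), 0L)
  expect_true(all(ds$fpkm[zero, ] == 0))

  expect_error(gen_expression_dataset(1,
                                      effects = list(effect_spec("a", 2),
                                                     effect_spec("b", 2)),
                                      seed = 1), "n_genes")
  expect_error(gen_expression_dataset(10,
                                      effects = list(effect_spec("a", 2),
                                                     effect_spec("a", 3)),
                                      seed = 1), "duplicate")
  expect_error(effect_spec("x", 0.5), "fold_change")
})

test_that("planted effects are recovered on average across replicate generations", {
  # Monte-Carlo oracle: direct ratio of the planted gene's values
  est <- vapply(1:200, function(i) {
    ds <- gen_expression_dataset(50,
                                 effects = list(effect_spec("G", -8, "10q22")),
                                 background_sd = 0.1, seed = 4000 + i)
    oracle_signed_ratio(ds$fpkm["G", "BEC40W"], ds$fpkm["G", "BEC20W"])
  }, numeric(1))
  expect_lt(abs(mean(est) - (-8)) / 8, 0.05)
})

test_that("generated annotation keeps background genes outside every window", {
  w <- default_windows()
  for (seed in 1:5) {
    ds <- gen_expression_dataset(300,
                                 effects = list(effect_spec("E1", 3, "2p22"),
                                                effect_spec("E2", -4, "16q22"),
                                                effect_spec("E3", 2, "background")),
                                 seed = seed)
    ann <- ds$annotation
    in_window <- unique(unlist(lapply(w, function(win) {
      extract_window(ann, win)$gene_id
    })))
    expect_setequal(in_window, c("E1", "E2"))
    # effect genes lie fully inside their declared window
    e1 <- ann[ann$gene_id == "E1", ]
    expect_true(e1$chrom == "2" && e1$start >= w[["2p22"]]$start &&
                  e1$end <= w[["2p22"]]$end)
  }
})

test_that("FISH cell generator reproduces noiseless state signatures", {
  g <- gen_fish_cells(50, fish_state_mix(normal = 1), seed = 3)
  expect_true(all(g$cells$red == 2 & g$cells$green == 2 & g$cells$fusion == 0))
  expect_true(all(g$truth == "normal"))

  gf <- gen_fish_cells(50, fish_state_mix(normal = 0, fusion = 1), seed = 3)
  expect_true(all(gf$cells$fusion >= 1))
  # default semantics: the fused pair consumes one red and one green
  expect_true(all(gf$cells$red == 1 & gf$cells$green == 1))
  gk <- gen_fish_cells(50, fish_state_mix(normal = 0, fusion = 1), seed = 3,
                       consume_parents = FALSE)
  expect_true(all(gk$cells$red == 2 & gk$cells$green == 2 & gk$cells$fusion == 1))

  gb <- gen_fish_cells(200, fish_state_mix(normal = 0, break_no_fusion = 1),
                       seed = 5)
  expect_true(all(pmax(gb$cells$red, gb$cells$green) == 3 &
                    pmin(gb$cells$red, gb$cells$green) == 2))
  gg <- gen_fish_cells(200, fish_state_mix(normal = 0, gain = 1), seed = 5)
  expect_true(all(gg$cells$red + gg$cells$green == 5 & gg$cells$fusion == 0))

  expect_identical(gen_fish_cells(100, fish_state_mix(fusion = 0.5, normal = 0.5),
                                  seed = 9),
                   gen_fish_cells(100, fish_state_mix(fusion = 0.5, normal = 0.5),
                                  seed = 9))
  expect_error(fish_state_mix(normal = 0.5, fusion = 0.4), "sum to 1")
  expect_error(fish_state_mix(dropout_prob = 1.2), "\\[0, 1\\]")
})

test_that("dropout and spurious overlap perturb counts as specified", {
  mix <- fish_state_mix(normal = 1, dropout_prob = 0.5)
  g <- gen_fish_cells(4000, mix, seed = 12)
  # each of the 4 true signals kept with probability 0.5
  expect_lt(abs(mean(g$cells$red + g$cells$green) - 2), 0.1)
  expect_true(any(g$cells$red < 2))

  mix2 <- fish_state_mix(normal = 1, spurious_overlap_prob = 0.2)
  g2 <- gen_fish_cells(4000, mix2, seed = 13)
  # each of the 2 potential red/green pairs converts with probability 0.2
  expect_lt(abs(mean(g2$cells$fusion) - 0.4), 0.05)
  # conversion conserves: red + fusion stays 2
  expect_true(all(g2$cells$red + g2$cells$fusion == 2))
})

test_that("karyotype set generator honors penetrance and serializes parseably", {
  base <- "46,XY"
  added <- list(parse_aberration("t(2;10;16)(p22;q22;q22)"),
                parse_aberration("+20"))
  all6 <- gen_karyotype_set(base, added, penetrance = 1, n_replicates = 6,
                            seed = 1)
  expect_true(all(grepl("t\\(2;10;16\\)", all6)))
  expect_true(all(grepl("\\+20", all6)))
  # gain adjusts the modal count
  expect_true(all(startsWith(all6, "47,XY")))

  none <- gen_karyotype_set(base, added, penetrance = 0, n_replicates = 4,
                            seed = 1)
  expect_true(all(none == format_karyotype(parse_karyotype(base))))

  many <- gen_karyotype_set(base, added, penetrance = 4 / 6,
                            n_replicates = 6000, seed = 5)
  expect_lt(abs(mean(grepl("t\\(2;10;16\\)", many)) - 4 / 6), 0.02)
  expect_identical(many,
                   gen_karyotype_set(base, added, penetrance = 4 / 6,
                                     n_replicates = 6000, seed = 5))
  # every generated string re-parses
  for (s in unique(many)) expect_s3_class(parse_karyotype(s), "karyotype")

  det <- gen_karyotype_set(base, added, penetrance = 0.5, n_replicates = 4,
                           carriers = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(grepl("t\\(", det), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("generators restore the caller's RNG state", {
  withr::with_seed(500, {
    before <- runif(1)
  })
  withr::with_seed(500, {
    invisible(gen_expression_dataset(50, seed = 1))
    invisible(gen_fish_cells(10, fish_state_mix(), seed = 2))
    after <- runif(1)
  })
  expect_identical(before, after)
})
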