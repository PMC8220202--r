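test_that("parse_karyotype maps every token of published-style strings", {
  k <- parse_karyotype("47,XY,add(4)(p16.1),add(7)(p22),i(8)(q10),+20")
  expect_equal(k$modal_count, 47L)
  expect_equal(k$sex_designation, "XY")
  expect_length(k$aberrations, 4L)
  expect_equal(vapply(k$aberrations, `[[`, character(1), "kind"),
               c("add", "add", "iso", "gain"))
  expect_equal(k$aberrations[[1]]$bands, "p16.1")

  k2 <- parse_karyotype("48,XY,i(8)(q10),t(2;10;16)(p22;q22;q22),+20,+20")
  expect_equal(k2$modal_count, 48L)
  t3 <- k2$aberrations[[2]]
  expect_equal(t3$kind, "translocation")
  expect_equal(t3$chromosomes, c("2", "10", "16"))
  expect_equal(t3$bands, c("p22", "q22", "q22"))
  # doubled gain preserved as two multiset entries
  expect_equal(sum(vapply(k2$aberrations, function(a) {
    a$kind == "gain" && a$chromosomes == "20"
  }, logical(1))), 2L)

  k3 <- parse_karyotype("46,XY")
  expect_length(k3$aberrations, 0L)

  # constructs outside the dialect and malformed tokens are named errors
  expect_error(parse_karyotype("46,XY,der(3)t(3;5)(q21;q31)"), "der")
  expect_error(parse_karyotype("46,XY,+20,inv(9)(p12q13)"),
               "position 4")
  expect_error(parse_karyotype("46,XY,t(2;10)(p22)"), "structural")
  expect_error(parse_karyotype("46"), "modal count and sex")
  expect_error(parse_karyotype("4x,XY"), "modal count")
  expect_error(parse_karyotype("46,XZ"), "sex designation")
})

test_that("parse/format round trip holds on all 12 replicate strings and dup/loss forms", {
  tab <- bec_karyotypes()
  for (s in c(tab$unexposed, tab$exposed)) {
    expect_identical(format_karyotype(parse_karyotype(s)),
                     gsub("[[:space:]]", "", s))
  }
  for (s in c("46,XY,dup(11)(q13q25)", "45,XY,-Y", "46,XX")) {
    expect_identical(format_karyotype(parse_karyotype(s)), s)
  }
  expect_identical(format_karyotype(karyotype(46, "XX")), "46,XX")
})

test_that("randomly generated karyotypes survive parse/format round trip", {
  withr::with_seed(101, {
    for (i in 1:50) {
      k <- random_karyotype()
      expect_equal(parse_karyotype(format_karyotype(k)), k)
    }
  })
})

test_that("match_aberration distinguishes band resolutions", {
  a <- parse_aberration("t(2;10;16)(p22;q22;q22)")
  b <- parse_aberration("t(2;10;16)(p22;q22;q21)")
  expect_false(match_aberration(a, b, "exact"))
  expect_true(match_aberration(a, b, "major_band"))
  expect_true(match_aberration(a, b, "chromosomes_only"))
  # major_band compares only the first band digit: q21 vs q32 differ
  expect_false(match_aberration(parse_aberration("add(7)(q21)"),
                                parse_aberration("add(7)(q32)"), "major_band"))
  # different chromosome order never matches
  expect_false(match_aberration(parse_aberration("t(2;10)(p22;q22)"),
                                parse_aberration("t(10;2)(q22;p22)"),
                                "chromosomes_only"))
})

test_that("match_aberration is reflexive, symmetric, and nested across resolutions", {
  withr::with_seed(202, {
    abs <- replicate(14, random_aberration(), simplify = FALSE)
    for (r in c("exact", "major_band", "chromosomes_only")) {
      for (a in abs) expect_true(match_aberration(a, a, r))
    }
    for (i in seq_along(abs)) {
      for (j in seq_along(abs)) {
        e <- match_aberration(abs[[i]], abs[[j]], "exact")
        m <- match_aberration(abs[[i]], abs[[j]], "major_band")
        c <- match_aberration(abs[[i]], abs[[j]], "chromosomes_only")
        expect_identical(e, match_aberration(abs[[j]], abs[[i]], "exact"))
        if (e) expect_true(m)
        if (m) expect_true(c)
      }
    }
  })
})

test_that("find_recurrent groups, counts multiplicity, and respects min_count", {
  exposed <- bec_karyotypes()$exposed
  rec <- find_recurrent(exposed, resolution = "chromosomes_only")
  t_row <- rec[grepl("^t\\(2;10;16\\)", rec$aberration), ]
  expect_equal(t_row$n_karyotypes, 4L)
  gain_row <- rec[rec$aberration == "+20", ]
  expect_equal(gain_row$n_karyotypes, 6L)
  expect_equal(gain_row$n_karyotypes_multiple, 4L)  # doubled +20 in 4 of 6
  expect_equal(gain_row$total_copies, 10L)

  # counts never exceed the number of input karyotypes
  expect_true(all(rec$n_karyotypes <= length(exposed)))
  # sorted by descending count
  expect_true(!is.unsorted(rev(rec$n_karyotypes)))

  # at exact resolution the q21/q22 translocation variants split
  rec_exact <- find_recurrent(exposed, resolution = "exact")
  t_exact <- rec_exact[grepl("^t\\(", rec_exact$aberration), ]
  expect_equal(sort(t_exact$n_karyotypes), c(1L, 3L))
  # ... and merge again at major_band
  rec_mb <- find_recurrent(exposed, resolution = "major_band")
  expect_equal(rec_mb$n_karyotypes[grepl("^t\\(", rec_mb$aberration)], 4L)

  expect_equal(nrow(find_recurrent(exposed, min_count = 5L)), 2L)
  expect_equal(nrow(find_recurrent(list())), 0L)

  single <- find_recurrent("47,XY,add(7)(p22),i(8)(q10),+20", min_count = 1L)
  expect_equal(nrow(single), 3L)
  expect_true(all(single$n_karyotypes == 1L))
})

test_that("diff_karyotypes reports the gained and lost multiset", {
  tab <- bec_karyotypes()
  d <- diff_karyotypes(tab$unexposed[1], tab$exposed[1], "chromosomes_only")
  expect_equal(vapply(d$gained, format_aberration, character(1)),
               c("+20", "t(2;10;16)(p22;q22;q22)"))
  expect_equal(vapply(d$lost, format_aberration, character(1)),
               c("add(4)(p16.1)", "add(7)(p22)"))

  k <- parse_karyotype(tab$exposed[1])
  d0 <- diff_karyotypes(k, k, "exact")
  expect_length(d0$gained, 0L)
  expect_length(d0$lost, 0L)
})

test_that("diff then re-apply reconstructs the target multiset", {
  ser <- function(abs) sort(vapply(abs, format_aberration, character(1)))
  withr::with_seed(303, {
    for (i in 1:25) {
      a <- random_karyotype(); b <- random_karyotype()
      d <- diff_karyotypes(a, b, "exact")
      lost_ser <- vapply(d$lost, format_aberration, character(1))
      kept <- a$aberrations
      for (s in lost_ser) {
        idx <- which(vapply(kept, format_aberration, character(1)) == s)[1]
        kept <- kept[-idx]
      }
      expect_equal(ser(c(kept, d$gained)), ser(b$aberrations))
    }
  })
})
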