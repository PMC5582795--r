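test_that("site calls use strict inequality and the ratio form is equivalent", {
  prof <- fake_profile(c(0.66, 0.68, 2 / 3, 0.0, 0.9))
  called <- call_divergent_sites(prof, cutoff = 0.67)
  expect_setequal(called$site, c(2L, 5L))
  called_r <- call_divergent_sites(prof, ratio_cutoff = 2)
  expect_setequal(called_r$site, called$site)
  expect_equal(called$Q, sort(called$Q, decreasing = TRUE))

  expect_equal(nrow(call_divergent_sites(fake_profile(rep(0, 5)))), 0L)
  expect_error(call_divergent_sites(prof, cutoff = 1.2), "cutoff")
  expect_error(call_divergent_sites(prof, cutoff = 0), "cutoff")
})

test_that("call sets shrink monotonically as the cutoff rises", {
  set.seed(19)
  prof <- fake_profile(runif(60))
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  ns <- vapply(cuts, function(ct) nrow(call_divergent_sites(prof, ct)), 1L)
  expect_true(all(diff(ns) <= 0))
})

test_that("conservation summaries report modal residues and normalized tallies", {
  fam <- toy_family()
  cons <- conservation_summary(fam$aln, fam$clusters, sites = c(5, 6))
  a5 <- cons[cons$site == 5 & cons$cluster == "A", ]
  expect_equal(a5$modal_residue, "F")
  expect_equal(a5$modal_fraction, 0.75)   # F,F,F,Y
  b6 <- cons[cons$site == 6 & cons$cluster == "B", ]
  expect_equal(b6$modal_residue, "S")
  expect_equal(b6$modal_fraction, 0.75)   # S,S,A,S
  for (tab in cons$residues) expect_equal(sum(tab), 1)
})

test_that("the type-II pattern check needs conservation plus a radical shift", {
  aln <- make_aln(
    a1 = "FDAKQ", a2 = "FDSKQ", a3 = "FDFKQ", a4 = "FDSKQ",
    b1 = "SEAQQ", b2 = "SEAQQ", b3 = "SEAQQ", b4 = "SEAQQ"
  )
  cl <- cluster_pair(paste0("a", 1:4), paste0("b", 1:4))
  chk <- type2_pattern_check(1:5, aln, cl)
  expect_true(chk$pattern[1])    # F vs S, both fixed: canonical
  expect_false(chk$pattern[2])   # D vs E: conserved change
  expect_false(chk$pattern[3])   # cluster 1 not conserved (F 1/4 ... mixed)
  expect_true(chk$pattern[4])    # K vs Q: radical, both fixed
  expect_false(chk$pattern[5])   # identical residues
  expect_equal(chk$change_class[2], "conserved")
  # threshold is honored
  chk9 <- type2_pattern_check(1:5, aln, cl, tau = 0.8)
  expect_equal(chk$pattern, chk9$pattern)
})

test_that("binding-site lists validate letters against the reference", {
  aln <- make_aln(ref = "MK-TFS", b1 = "MKATFS", b2 = "MKATFS",
                  c1 = "MKATFS", c2 = "MKATFS", c3 = "MKATFS")
  good <- tibble::tibble(position = c(1L, 4L), residue = c("M", "F"),
                         label = "x")
  expect_silent(validate_binding_sites(good, aln, "ref"))
  bad <- tibble::tibble(position = 4L, residue = "S", label = "x")
  expect_error(validate_binding_sites(bad, aln, "ref"), "mismatch")
  far <- tibble::tibble(position = 99L, residue = "M", label = "x")
  expect_error(validate_binding_sites(far, aln, "ref"), "outside")
})

test_that("the packaged binding-site fixture loads with 12 positions", {
  path <- system.file("extdata", "mk0893_binding_sites_synthetic.tsv",
                      package = "paradiv")
  bs <- read_binding_sites(path)
  expect_equal(nrow(bs), 12L)
  expect_true(all(c(345L, 405L) %in% bs$position))
})

test_that("chi-square matches the closed form on random 2x2 tables", {
  set.seed(27)
  for (i in 1:15) {
    a <- sample(0:6, 1); b <- sample(1:12, 1)
    cc <- sample(1:15, 1); d <- sample(20:400, 1)
    if ((a + b) == 0 || (a + cc) == 0) next
    s <- sets_from_table(a, b, cc, d)
    res <- enrichment_test(s$divergent, s$binding, s$total)
    expect_equal(res$p_value,
                 pchisq(chisq_closed(a, b, cc, d), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(unname(res$statistic), chisq_closed(a, b, cc, d),
                 tolerance = 1e-10)
    expect_equal(sum(res$table), s$total)
  }
})

test_that("Fisher exact equals the hypergeometric enumeration", {
  set.seed(53)
  for (i in 1:12) {
    a <- sample(0:4, 1); b <- sample(1:8, 1)
    cc <- sample(1:8, 1); d <- sample(10:80, 1)
    s <- sets_from_table(a, b, cc, d)
    res <- enrichment_test(s$divergent, s$binding, s$total, method = "fisher")
    expect_equal(res$p_value, fisher_enum(a, b, cc, d), tolerance = 1e-9)
  }
  # binding entirely inside divergent
  s <- sets_from_table(5, 10, 0, 100)
  res <- enrichment_test(s$divergent, s$binding, s$total, method = "fisher")
  expect_equal(res$p_value, fisher_enum(5, 10, 0, 100), tolerance = 1e-9)
})

test_that("enrichment is order-invariant, deduplicated, and guards lengths", {
  div <- c(5L, 1L, 9L, 1L)
  bind <- c(9L, 2L, 5L)
  r1 <- enrichment_test(div, bind, 50)
  r2 <- enrichment_test(rev(div), sample(bind), 50)
  expect_equal(r1$table, r2$table)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(enrichment_test(c(1L, 60L), bind, 50), "total_length")

  # no association when overlap matches expectation
  g <- glance(r1)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_divergent, 3L)
  td <- tidy(r1)
  expect_equal(sum(td$n), 50)
  expect_equal(sum(td$expected), sum(td$n))
})

test_that("small expected counts trigger the Fisher suggestion note", {
  s <- sets_from_table(2, 6, 10, 459)
  res <- enrichment_test(s$divergent, s$binding, s$total)
  expect_match(res$note, "Fisher")
  expect_true(is.finite(res$fisher_p))
})
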