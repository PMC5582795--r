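test_that("the four-group scheme partitions the alphabet 3/2/7/8", {
  scheme <- aa_group_scheme()
  expect_length(scheme, 20)
  sizes <- sort(table(scheme), decreasing = TRUE)
  expect_equal(as.integer(sizes), c(8L, 7L, 3L, 2L))
  expect_equal(unname(scheme[c("K", "R", "H")]), rep("positive", 3))
  expect_equal(unname(scheme[c("D", "E")]), rep("negative", 2))
  expect_equal(unname(scheme["S"]), "hydrophilic")
  expect_equal(unname(scheme["F"]), "hydrophobic")
  expect_error(aa_group_scheme(list(a = c("A", "C"), b = c("C", "D"))),
               "overlap|partition")
})

test_that("replacement classification matches the scheme and is symmetric", {
  expect_equal(classify_change("D", "E"), "conserved")
  expect_equal(classify_change("F", "S"), "radical")
  expect_equal(classify_change("K", "Q"), "radical")
  expect_equal(classify_change("N", "D"), "radical")
  expect_equal(classify_change("K", "K"), "identical")
  expect_error(classify_change("K", "Z"), "alphabet")

  set.seed(3)
  a <- sample(c("A","C","D","E","F","K","R","S","T","W"), 25, replace = TRUE)
  b <- sample(c("A","C","D","E","F","K","R","S","T","W"), 25, replace = TRUE)
  expect_equal(classify_change(a, b), classify_change(b, a))
})

test_that("the neutral radical fraction is brute-forced over all 190 pairs", {
  # independent oracle: plain nested loop over the letter pairs
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
  groups <- c(K="p",R="p",H="p", D="n",E="n",
              S="h",T="h",N="h",Q="h",C="h",G="h",P="h",
              A="b",I="b",L="b",M="b",F="b",W="b",V="b",Y="b")
  radical <- 0; total <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    total <- total + 1
    if (groups[letters20[i]] != groups[letters20[j]]) radical <- radical + 1
  }
  expect_equal(total, 190)
  expect_equal(radical, 137)
  expect_equal(scheme_radical_fraction(), 137 / 190, tolerance = 1e-12)

  expect_equal(scheme_radical_fraction(
    structure(setNames(rep("one", 20), letters20), class = "aa_group_scheme")), 0)
  expect_equal(scheme_radical_fraction(
    structure(setNames(letters20, letters20), class = "aa_group_scheme")), 1)
})

test_that("early profiles classify ancestral pairs with tie propagation", {
  tab <- tibble::tibble(
    site = 1:4, ref_pos = 1:4, x1 = 0L, x2 = 0L,
    a1 = c("K", "N", "K", "D"), a2 = c("K", "D", "Q", "E"),
    tie1 = c(FALSE, FALSE, TRUE, FALSE), tie2 = FALSE
  )
  prof <- early_profile(tab)
  expect_equal(prof$class, c("N", "R", "R", "C"))
  expect_equal(prof$tie, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("type-II f1 vanishes off radical sites and both densities normalize", {
  params <- list(alpha = 1, m1 = 0.8, m2 = 0.8, d_e = 0.5,
                 pi_r = 137 / 190, epsilon = 0.1)
  ff_n <- type2_site_likelihoods("N", 3L, 1L, params)
  expect_equal(ff_n$f1, 0)
  ff_c <- type2_site_likelihoods("C", 0L, 0L, params)
  expect_equal(ff_c$f1, 0)

  grid <- expand.grid(x1 = 0:80, x2 = 0:80, cls = c("N", "C", "R"),
                      stringsAsFactors = FALSE)
  ff <- type2_site_likelihoods(grid$cls, grid$x1, grid$x2, params)
  expect_equal(sum(ff$f0), 1, tolerance = 1e-6)
  expect_equal(sum(ff$f1), 1, tolerance = 1e-6)  # mass all on c = R
  expect_equal(sum(0.76 * ff$f0 + 0.24 * ff$f1), 1, tolerance = 1e-6)
})

test_that("posteriors depend only on (class, x1, x2) and favor conserved R sites", {
  params <- list(theta = 0.25, alpha = 1, m1 = 1, m2 = 1, d_e = 0.5,
                 pi_r = 137 / 190, epsilon = 0.1)
  prof <- tibble::tibble(
    site = 1:6, ref_pos = 1:6,
    class = c("R", "N", "C", "R", "R", "R"),
    x1 = c(0L, 0L, 0L, 3L, 0L, 0L),
    x2 = c(0L, 0L, 0L, 3L, 0L, 4L)
  )
  post <- type2_posteriors(prof, params)
  expect_equal(post$Q[2], 0)   # N site
  expect_equal(post$Q[3], 0)   # C site
  expect_equal(post$Q[1], post$Q[5])       # identical (class, counts)
  expect_gt(post$Q[1], post$Q[4])          # (0,0) beats (3,3) under epsilon<1
  expect_gt(post$Q[1], post$Q[6])
  expect_equal(post$R, post$Q / (1 - post$Q))

  # permuting sites permutes posteriors
  perm <- c(3, 1, 6, 2, 5, 4)
  post_perm <- type2_posteriors(prof[perm, ], params)
  expect_equal(post_perm$Q, post$Q[perm])
})

test_that("a profile with no radical sites pins theta at zero with a flag", {
  prof <- tibble::tibble(
    site = 1:120, ref_pos = 1:120,
    class = rep(c("N", "C"), 60),
    x1 = rep(c(0L, 1L), 60), x2 = rep(c(1L, 0L), 60)
  )
  fit <- fit_type2(prof)
  expect_equal(fit$theta, 0)
  expect_true("no_radical_sites" %in% fit$flags)
  expect_equal(fit$lrt, 0)
  expect_equal(fit$p_value, 1)
})

test_that("type-II recovery and the called-fraction monotonicity hold in simulation", {
  thetas <- c(0.1, 0.35)
  called_frac <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    fam <- simulate_family(sim_config(L = 800, theta2 = thetas[i],
                                      seed = 300 + i))
    prof <- early_profile(truth_count_table(fam))
    fit <- fit_type2(prof)
    expect_lt(abs(fit$theta - thetas[i]), 0.12)
    post <- type2_posteriors(prof, fit)
    called_frac[i] <- mean(post$Q > 0.67)
  }
  expect_lt(called_frac[1], called_frac[2])
})

test_that("empirical pi_r mode uses the observed radical share", {
  fam <- simulate_family(sim_config(L = 600, theta2 = 0.2, seed = 41))
  prof <- early_profile(truth_count_table(fam))
  fit <- fit_type2(prof, pi_r = "empirical")
  n_r <- sum(prof$class == "R"); n_c <- sum(prof$class == "C")
  expect_equal(fit$extra$pi_r, n_r / (n_r + n_c))
  expect_true(is.finite(fit$theta))
})
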