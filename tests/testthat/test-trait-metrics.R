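test_that("CWM matches hand computations and is convex in species means", {
  tt <- trait_table(tibble::tibble(
    community = "c1", species = c("A", "A", "B", "B"),
    mass = c(2, 2, 6, 6)))
  expect_equal(cwm(tt)$cwm, 4)

  one <- trait_table(tibble::tibble(community = "c1", species = "A",
                                    mass = c(2, 4)))
  expect_equal(cwm(one)$cwm, 3)

  # unequal abundance: weights are individual counts
  uneq <- trait_table(tibble::tibble(
    community = "c1", species = c("A", "A", "A", "B"),
    mass = c(2, 2, 2, 6)))
  expect_equal(cwm(uneq)$cwm, 0.75 * 2 + 0.25 * 6)

  # local and regional modes agree when species means are homogeneous
  homo <- trait_table(tibble::tibble(
    community = rep(c("c1", "c2"), each = 2),
    species = rep(c("A", "B"), 2),
    mass = c(2, 6, 2, 6)))
  expect_equal(cwm(homo, mode = "local")$cwm,
               cwm(homo, mode = "regional")$cwm)

  # convexity on random tables
  for (seed in 1:5) {
    tt <- random_table(seed = seed + 40)
    w <- cwm(tt)
    means <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(as.data.frame(tt)),
                      community, species),
      m = mean(mass), .groups = "drop")
    rng <- dplyr::summarise(dplyr::group_by(means, community),
                            lo = min(m), hi = max(m), .groups = "drop")
    j <- dplyr::left_join(w, rng, by = "community")
    expect_true(all(j$cwm >= j$lo - 1e-12 & j$cwm <= j$hi + 1e-12))
  }
})

test_that("kernel densities are normalized, shared-grid, and consistent", {
  set.seed(2)
  tt <- trait_table(tibble::tibble(
    community = rep(c("c1", "c2"), each = 200),
    species = "A",
    mass = exp(c(rnorm(200, 0, .3), rnorm(200, 1, .3)))))
  lt <- log_transform(tt)
  kd <- trait_kde(lt, "mass")
  expect_gte(length(unique(kd$x)), 512)
  expect_true(all(kd$density >= 0))
  for (k in c("c1", "c2")) {
    sub <- kd[kd$community == k, ]
    expect_equal(sum(diff(sub$x) * (sub$density[-1] +
                                      sub$density[-nrow(sub)]) / 2),
                 1, tolerance = 1e-3)
  }

  # duplicating every observation leaves the density unchanged (the kernel
  # mixture is identical at a fixed bandwidth)
  dup <- trait_table(tibble::tibble(
    community = "c1", species = "A",
    mass = rep(exp(rnorm(100, 0, .2)), 2)))
  kd1 <- trait_kde(log_transform(dup), "mass", bw = 0.1)
  half <- trait_table(as.data.frame(dup)[1:100, c("community", "species",
                                                  "mass")])
  kd2 <- trait_kde(log_transform(half), "mass", bw = 0.1)
  expect_equal(kd1$density, kd2$density, tolerance = 1e-10)

  # KDE converges to the true standard normal density
  set.seed(3)
  big <- trait_table(tibble::tibble(
    community = "c1", species = "A", mass = exp(rnorm(1e4))))
  kdb <- trait_kde(log_transform(big), "mass")
  expect_lt(max(abs(kdb$density - dnorm(kdb$x))), 0.05)

  # zero within-community variance: error points at the bandwidth override,
  # and supplying one succeeds
  degen <- log_transform(trait_table(tibble::tibble(
    community = c("c1", "c1", "c1", "c2", "c2"), species = "A",
    mass = c(2, 2, 2, 1, 4))))
  expect_error(trait_kde(degen, "mass"), "bw")
  kd_fix <- trait_kde(degen, "mass", bw = 0.2)
  expect_true(all(is.finite(kd_fix$density)))
})

test_that("overlap is a unit-diagonal symmetric similarity in [0,1]", {
  set.seed(4)
  x <- exp(rnorm(500, 0, .4))
  tt <- trait_table(tibble::tibble(
    community = rep(c("a", "b", "c"), each = 500),
    species = "A",
    mass = c(x, x, exp(rnorm(500, 5, .4)))))
  kd <- trait_kde(log_transform(tt), "mass")
  ov <- kde_overlap(kd)
  m <- overlap_matrix(ov)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= 0 & m <= 1))
  # identical samples overlap fully; far-separated supports do not
  expect_equal(m["a", "b"], 1, tolerance = 1e-3)
  expect_lt(m["a", "c"], 0.01)

  expect_error(overlap(kd[kd$community == "a", ][1:100, ],
                       kd[kd$community == "b", ]),
               "grid")
})

test_that("overlap of N(0,1) and N(2,1) estimates the closed-form 2*pnorm(-1)", {
  set.seed(5)
  tt <- trait_table(tibble::tibble(
    community = rep(c("lo", "hi"), each = 1e4),
    species = "A",
    mass = exp(c(rnorm(1e4, 0, 1), rnorm(1e4, 2, 1)))))
  kd <- trait_kde(log_transform(tt), "mass")
  ov <- kde_overlap(kd)
  expect_lt(abs(ov$overlap - 2 * pnorm(-1)), 0.02)
})

test_that("overlap decay regression behaves on degenerate and linear inputs", {
  ov <- structure(tibble::tibble(
    community_a = c("a", "a", "b"),
    community_b = c("b", "c", "c"),
    overlap = c(0.9, 0.8, 0.7)),
    trait = "mass", class = c("overlap_tbl", class(tibble::tibble())))
  env <- tibble::tibble(community = c("a", "b", "c"),
                        elevation = c(100, 300, 600))
  # distances 200, 500, 300; overlaps chosen non-linear in distance
  fit <- overlap_decay(ov, env)
  expect_s3_class(fit, "tf_ols")

  # exactly linear in distance -> R^2 = 1, recovered slope
  ov$overlap <- 1 - 1e-3 * c(200, 500, 300)
  fit2 <- overlap_decay(ov, env)
  expect_equal(fit2$slope, -1e-3, tolerance = 1e-10)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)

  # constant overlap -> zero slope, non-positive adjusted R^2
  ov$overlap <- rep(0.5, 3)
  fit3 <- overlap_decay(ov, env)
  expect_equal(fit3$slope, 0, tolerance = 1e-12)
  expect_lte(fit3$adj_r2, 0)
})

test_that("taxonomic rarefaction matches enumeration and is monotone concave", {
  # 2 species x 2 individuals, m = 2: exhaustive enumeration gives 5/3
  tt <- trait_table(tibble::tibble(
    community = "c1", species = c("A", "A", "B", "B"),
    mass = c(1, 1, 1, 1) * 2))
  cur <- rarefaction(tt, "c1", "taxonomic", m_grid = c(1, 2, 4))
  expect_equal(cur$value[cur$m == 1], 1)
  expect_equal(cur$value[cur$m == 2],
               enumerate_rarefaction(c("A", "A", "B", "B"), 2))
  expect_equal(cur$value[cur$m == 2], 5 / 3)
  expect_equal(cur$value[cur$m == 4], 2) # full sample: observed richness

  # larger random community: enumeration oracle at several depths
  set.seed(6)
  sp <- sample(paste0("s", 1:4), 9, replace = TRUE)
  tt2 <- trait_table(tibble::tibble(community = "k", species = sp,
                                    mass = runif(9) + 1))
  cur2 <- rarefaction(tt2, "k", "taxonomic", m_grid = 1:9)
  for (m in c(2, 3, 5, 9)) {
    expect_equal(cur2$value[cur2$m == m], enumerate_rarefaction(sp, m),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(cur2$value) > -1e-12))          # nondecreasing
  expect_true(all(diff(diff(cur2$value)) < 1e-12))      # concave
})

test_that("functional rarefaction converges to the community trait variance", {
  set.seed(7)
  tt <- trait_table(tibble::tibble(
    community = "c1", species = rep(c("A", "B"), each = 30),
    mass = exp(rnorm(60, 0, 0.5))))
  cur <- rarefaction(tt, "c1", "functional", m_grid = c(10, 30, 60),
                     n_resamples = 200, seed = 8)
  full_var <- var(log(tt$mass))
  # at m = n the resample is the full community
  expect_equal(cur$value[cur$m == 60], var(tt$mass), tolerance = 1e-10)
  expect_true(all(is.finite(cur$value)))
})

test_that("rarefied richness uses the smallest community as common depth", {
  tt <- random_table(n_communities = 3, n_species = 6, n_per_pop = 5,
                     seed = 50)
  rr <- rarefied_richness(tt)
  sizes <- table(as.data.frame(tt)$community)
  expect_true(all(rr$m == min(sizes)))
  expect_true(all(rr$richness_rarefied <= rr$richness_observed + 1e-9))
})
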