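make_structured <- function(seed = 3, sw = 0.02) {
  # strong internal structure: species internally near-constant
  set.seed(seed)
  rows <- expand.grid(community = paste0("c", 1:4),
                      species = paste0("s", 1:8),
                      rep = 1:8, stringsAsFactors = FALSE)
  means <- setNames(rnorm(8, 0, 1), paste0("s", 1:8))
  rows$mass <- exp(means[rows$species] + rnorm(nrow(rows), 0, sw))
  trait_table(rows[c("community", "species", "mass")])
}

test_that("each randomization scheme conserves what it must", {
  tt <- random_table(n_communities = 4, n_species = 6, seed = 21)
  df <- as.data.frame(tt)

  for (i in 1:5) {
    sh <- as.data.frame(randomize_table(tt, "shuffle_within_community",
                                        seed = i))
    for (k in unique(df$community)) {
      # trait multiset per community unchanged
      expect_equal(sort(sh$mass[sh$community == k]),
                   sort(df$mass[df$community == k]))
      # per-species abundances unchanged
      expect_equal(sort(table(sh$species[sh$community == k])),
                   sort(table(df$species[df$community == k])))
    }

    ri <- as.data.frame(randomize_table(tt, "draw_from_regional_individuals",
                                        seed = i))
    expect_equal(table(ri$community), table(df$community))
    expect_equal(sort(ri$mass), sort(df$mass))

    pm <- as.data.frame(
      randomize_table(tt, "draw_from_regional_population_means", seed = i))
    pops <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(df), community, species),
      mass = mean(mass), .groups = "drop")
    expect_equal(sort(pm$mass), sort(pops$mass))
    expect_equal(unname(table(pm$community)), unname(table(pops$community)))
  }

  # determinism
  expect_identical(
    as.data.frame(randomize_table(tt, "shuffle_within_community", seed = 9)),
    as.data.frame(randomize_table(tt, "shuffle_within_community", seed = 9)))
})

test_that("SES output is well-formed and seed-stable", {
  tt <- log_transform(random_table(n_communities = 3, n_species = 5,
                                   n_per_pop = 5, seed = 30))
  res <- tstat_ses(tt, n_iter = 99, seed = 5)
  expect_s3_class(res, "tstat_ses")
  expect_equal(nrow(res), 3 * 3) # 3 communities x 3 metrics, 1 trait
  expect_true(all(res$envelope_lo <= res$envelope_hi, na.rm = TRUE))
  ok <- !is.na(res$ses)
  expect_equal(res$ses[ok],
               ((res$observed - res$null_mean) / res$null_sd)[ok])
  res2 <- tstat_ses(tt, n_iter = 99, seed = 5)
  expect_identical(res, res2)
  # per-(trait, metric) streams: restricting the request reproduces the cells
  sub <- tstat_ses(tt, metrics = "T_IC_IR", n_iter = 99, seed = 5)
  expect_equal(sub, res[res$metric == "T_IC_IR", ], ignore_attr = TRUE)
})

test_that("SES is invariant to adding a constant on the analysis scale", {
  tt <- log_transform(random_table(n_communities = 3, n_species = 5,
                                   seed = 31))
  shifted <- tt
  shifted$mass <- shifted$mass + 5
  a <- tstat_ses(tt, n_iter = 99, seed = 3)
  b <- tstat_ses(shifted, n_iter = 99, seed = 3)
  expect_equal(a$ses, b$ses, tolerance = 1e-8)
  expect_equal(a$observed, b$observed, tolerance = 1e-8)
})

test_that("strong internal structure drives SES of T_IP_IC far below its envelope", {
  tt <- log_transform(make_structured(sw = 0.02))
  res <- tstat_ses(tt, metrics = "T_IP_IC", n_iter = 199, seed = 4)
  expect_true(all(res$ses < -3))
  expect_true(all(res$observed < res$envelope_lo))
  expect_true(all(res$significant))
})

test_that("null data give |SES| < 2 in about the nominal fraction of cells", {
  # traits drawn independently of species and community: every scheme's null
  # generating process, so SES should behave like a standard score
  n_rep <- 40
  inside <- matrix(NA, n_rep, 3,
                   dimnames = list(NULL, c("T_IP_IC", "T_IC_IR", "T_PC_PR")))
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    rows <- expand.grid(community = paste0("c", 1:4),
                        species = paste0("s", 1:6),
                        rep = 1:5, stringsAsFactors = FALSE)
    rows$mass <- exp(rnorm(nrow(rows), 0, 0.4))
    tt <- log_transform(trait_table(rows[c("community", "species", "mass")]))
    res <- tstat_ses(tt, n_iter = 199, seed = r)
    for (m in colnames(inside)) {
      inside[r, m] <- mean(abs(res$ses[res$metric == m]) < 2, na.rm = TRUE)
    }
  }
  # nominal ~95.4%; allow generous binomial slack at 40 replicates x 4 cells
  expect_true(all(colMeans(inside) >= 0.87))
})

test_that("richness-preserving regional null moves whole populations", {
  # species unique to one community so population identity is unambiguous
  set.seed(77)
  rows <- data.frame(
    community = rep(c("c1", "c2", "c3"), times = c(6, 9, 12)),
    species = rep(paste0("s", 1:9), times = c(2, 2, 2, 3, 3, 3, 4, 4, 4)))
  rows$mass <- exp(rnorm(nrow(rows), 0, 0.3))
  tt <- trait_table(rows)
  df <- as.data.frame(tt)
  for (i in 1:5) {
    rp <- as.data.frame(randomize_table(tt, "draw_from_regional_populations",
                                        seed = i))
    # regional trait multiset conserved
    expect_equal(sort(rp$mass), sort(df$mass))
    # populations move whole: each species' individuals share one community
    expect_true(all(tapply(rp$community, rp$species,
                           function(k) length(unique(k))) == 1))
    # per-community population (richness) counts conserved: 3 each
    expect_equal(unname(table(tapply(rp$community, rp$species, unique))),
                 rep(3L, 3), ignore_attr = TRUE)
  }
  # SES engine accepts the variant and stays seed-stable
  lt <- log_transform(tt)
  a <- tstat_ses(lt, metrics = "T_IC_IR", n_iter = 99, seed = 2,
                 regional_null = "populations")
  b <- tstat_ses(lt, metrics = "T_IC_IR", n_iter = 99, seed = 2,
                 regional_null = "populations")
  expect_identical(a, b)
  expect_true(all(is.finite(a$ses)))
})
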