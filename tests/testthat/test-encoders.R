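test_that("composition encoder matches degenerate and uniform cases", {
  v <- aac("AAAA")
  expect_equal(unname(v["AAC_A"]), 1)
  expect_equal(sum(v), 1)
  v2 <- aac("ACDE")
  expect_equal(unname(v2[c("AAC_A", "AAC_C", "AAC_D", "AAC_E")]), rep(0.25, 4))
  expect_equal(sum(v2 > 0), 4L)
  expect_error(aac(""), "non-empty")
})

test_that("composition encoder matches a letter-count oracle on random sequences", {
  set.seed(10)
  for (rep in 1:20) {
    s <- random_sequence(200)
    v <- aac(s)
    chars <- strsplit(s, "")[[1]]
    oracle <- vapply(AA, function(a) sum(chars == a) / 200, numeric(1))
    expect_equal(unname(v), unname(oracle), tolerance = 1e-14)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("AAIndex-weighted composition follows the composition-matrix product", {
  path <- tmp_aaindex(n_props = 3L, include_na = FALSE)
  tab <- read_aaindex1(path)
  # homopolymer: F_j equals the property's value for that residue
  fC <- aaindex_aac(strrep("C", 30), tab)
  expect_equal(unname(fC), unname(tab$values["C", ]))
  # every residue once: F_j is the property mean
  all20 <- paste(AA, collapse = "")
  expect_equal(unname(aaindex_aac(all20, tab)),
               unname(colMeans(tab$values)))
  # random sequences vs explicit double-loop oracle
  set.seed(11)
  for (rep in 1:10) {
    s <- random_sequence(120)
    got <- aaindex_aac(s, tab)
    comp <- aac(s)
    oracle <- vapply(colnames(tab$values), function(j) {
      sum(vapply(seq_len(20), function(i) comp[i] * tab$values[i, j],
                 numeric(1)))
    }, numeric(1))
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  }
})

test_that("weighted composition is linear in composition under concatenation", {
  path <- tmp_aaindex(n_props = 4L, include_na = FALSE)
  tab <- read_aaindex1(path)
  set.seed(12)
  a <- random_sequence(80); b <- random_sequence(40)
  lhs <- aaindex_aac(paste0(a, b), tab)
  rhs <- (80 * aaindex_aac(a, tab) + 40 * aaindex_aac(b, tab)) / 120
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("sequence entropy spans its analytic range and matches the formula", {
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy(paste(AA, collapse = "")), log2(20))
  set.seed(13)
  for (rep in 1:10) {
    s <- random_sequence(150)
    p <- aac(s); p <- p[p > 0]
    expect_equal(shannon_entropy(s), -sum(p * log2(p)), tolerance = 1e-12)
    h <- shannon_entropy(s)
    expect_gte(h, 0); expect_lte(h, log2(20))
  }
})

test_that("hydropathy uses the published scale and averages per residue", {
  expect_equal(kd_hydropathy("IIII"), 4.5)
  expect_equal(kd_hydropathy("RRRR"), -4.5)
  scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
             E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
             M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
             Y = -1.3, V = 4.2)
  set.seed(14)
  for (rep in 1:10) {
    s <- random_sequence(90)
    oracle <- mean(scale[strsplit(s, "")[[1]]])
    expect_equal(kd_hydropathy(s), oracle, tolerance = 1e-12)
  }
})

test_that("charge features satisfy their identities", {
  expect_equal(charge_features("DEKR"), c(FCR = 1, NCPR = 0))
  expect_equal(charge_features("DDDD"), c(FCR = 1, NCPR = -1))
  expect_equal(charge_features("AAAA"), c(FCR = 0, NCPR = 0))
  # histidine flag
  expect_equal(unname(charge_features("HHHH")["FCR"]), 0)
  expect_equal(unname(charge_features("HHHH", histidine_charged = TRUE)["FCR"]), 1)
  set.seed(15)
  for (rep in 1:10) {
    cf <- charge_features(random_sequence(70))
    expect_lte(abs(cf[["NCPR"]]), cf[["FCR"]])
    expect_lte(cf[["FCR"]], 1)
  }
})

test_that("composition features are invariant under sequence permutation", {
  set.seed(16)
  s <- random_sequence(100)
  sp <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aac(s), aac(sp))
  expect_equal(shannon_entropy(s), shannon_entropy(sp))
  expect_equal(kd_hydropathy(s), kd_hydropathy(sp))
  expect_equal(charge_features(s), charge_features(sp))
})

test_that("multimodal vector has 27 slots with AAC first and internal features last", {
  recs <- small_records(3L)
  zp <- zero_provider()
  v <- multimodal_vector(recs[1, ], zp)
  expect_length(v, 27L)
  expect_identical(names(v)[1:20], paste0("AAC_", AA))
  expect_equal(unname(v[21:25]), rep(0, 5))
  expect_equal(unname(v[["hydropathy"]]), kd_hydropathy(recs$sequence[1]))
  expect_equal(unname(v[["entropy"]]), shannon_entropy(recs$sequence[1]))
})

test_that("provider lookups are by id, not row order", {
  recs <- small_records(3L)
  tab <- gen_provider_table(recs, seed = 4L)
  v1 <- multimodal_vector(recs[2, ], feature_provider(tab))
  v2 <- multimodal_vector(recs[2, ], feature_provider(tab[rev(seq_len(nrow(tab))), ]))
  expect_identical(v1, v2)
})

test_that("provider errors list missing ids and features", {
  recs <- small_records(2L)
  tab <- gen_provider_table(recs, seed = 4L)
  prov <- feature_provider(tab)
  expect_error(provider_lookup(prov, "nope", "Kappa"), "nope")
  expect_error(provider_lookup(prov, recs$id[1], "unheard_of"), "unheard_of")
})

test_that("analysis vector has the 12 panel slots consistent with the standalone encoders", {
  recs <- small_records(2L)
  prov <- feature_provider(gen_provider_table(recs, seed = 4L))
  v <- analysis_vector(recs[1, ], prov)
  expect_length(v, 12L)
  cf <- charge_features(recs$sequence[1])
  expect_equal(unname(v[["FCR"]]), unname(cf[["FCR"]]))
  expect_equal(unname(v[["NCPR"]]), unname(cf[["NCPR"]]))
  expect_equal(unname(v[["hydropathy"]]), kd_hydropathy(recs$sequence[1]))
  expect_equal(unname(v[["entropy"]]), shannon_entropy(recs$sequence[1]))
  # zero provider leaves only internal slots nonzero
  vz <- analysis_vector(recs[1, ], zero_provider())
  ext <- setdiff(names(vz), c("FCR", "NCPR", "hydropathy", "entropy"))
  expect_equal(unname(vz[ext]), rep(0, length(ext)))
})

test_that("feature tables stack rows deterministically with ids as row names", {
  recs <- small_records(4L)
  t1 <- feature_table(recs, function(r) aac(r$sequence))
  t2 <- feature_table(recs, function(r) aac(r$sequence))
  expect_identical(t1, t2)
  expect_identical(rownames(t1), recs$id)
})
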