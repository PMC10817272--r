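test_that("diagnosis codes group by 3-character prefix, idempotently", {
  expect_identical(group_diagnosis("F43.10"), "DX:F43")
  expect_identical(group_diagnosis("F10.20"), "DX:F10")
  expect_identical(group_diagnosis("309.81"), "DX:309")  # same rule for ICD-9
  expect_identical(group_diagnosis("k21.9"), "DX:K21")   # case fold
  expect_identical(group_diagnosis(group_diagnosis("F43.10")), "DX:F43")
  expect_error(group_diagnosis("F4"), "shorter than 3")
})

test_that("drug names map case-insensitively; unmapped names return NA", {
  dm <- default_drug_map()
  expect_identical(map_drug("enalapril", dm), "RX:DB00584")
  expect_identical(map_drug("ENALAPRIL", dm), "RX:DB00584")
  expect_true(is.na(map_drug("unknownium", dm)))
  expect_identical(map_drug(c("oxycodone", "x"), dm), c("RX:DB00497", NA))
})

test_that("lab filtering keeps abnormal flags above the frequency floor", {
  mk_sample <- function(n_ab, name, flag = "HIGH") {
    visits <- lapply(seq_len(n_ab), function(i)
      list(days_before = i, dx = character(0), rx = character(0),
           lab = data.frame(name = name, flag = flag, stringsAsFactors = FALSE)))
    structure(list(patient_id = name, visits = visits), class = "cohort_sample")
  }
  samples <- list(mk_sample(99, "BELOW"), mk_sample(100, "AT"),
                  mk_sample(120, "NORMONLY", flag = "NORMAL"))
  fl <- filter_labs(samples, min_freq = 100)
  expect_false("BELOW" %in% fl$retained)   # 99 abnormal events: dropped
  expect_true("AT" %in% fl$retained)       # exactly 100: retained
  expect_false("NORMONLY" %in% fl$retained)
  expect_equal(unname(fl$counts["BELOW"]), 99)
})

test_that("SDoH coding yields quintile and demographic tokens plus z-scores", {
  sdoh <- data.frame(zip5 = sprintf("%05d", 1:10), f = 1:10,
                     stringsAsFactors = FALSE)
  samples <- lapply(1:10, function(i) structure(list(
    patient_id = paste0("P", i), index_date = day0 + 100,
    static = list(sex = "F", race = "WHITE", birth_year = 1975,
                  zip5 = sprintf("%05d", i)),
    visits = list()), class = "cohort_sample"))
  enc <- encode_sdoh(samples, sdoh)
  # median value sits in Q3; extremes in Q1/Q5
  expect_true("SDOH:f:Q3" %in% enc$tokens[[5]])
  expect_true("SDOH:f:Q1" %in% enc$tokens[[1]])
  expect_true("SDOH:f:Q5" %in% enc$tokens[[10]])
  expect_true(all(c("SEX:F", "RACE:WHITE", "AGE:40") %in% enc$tokens[[1]]))
  expect_equal(mean(enc$covariates[, "f"]), 0, tolerance = 1e-12)
  expect_equal(sd(enc$covariates[, "f"]), 1, tolerance = 1e-12)

  # all-equal feature: everyone lands in Q1 by the rank tie rule
  sdoh$f <- 5
  enc2 <- encode_sdoh(samples, sdoh)
  expect_true(all(vapply(enc2$tokens, function(t) "SDOH:f:Q1" %in% t,
                         logical(1))))

  # missing zip: single missing token, NA covariates
  samples[[1]]$static$zip5 <- "99999"
  enc3 <- encode_sdoh(samples, sdoh)
  expect_identical(setdiff(enc3$tokens[[1]],
                           c("SEX:F", "RACE:WHITE", "AGE:40")), "SDOH:MISSING")
  expect_true(is.na(enc3$covariates[1, "f"]))
})

test_that("quintile bins are balanced within one for untied features", {
  for (n in c(10, 23, 57)) {
    b <- seqrisk:::quintile_bin(rnorm(n))
    expect_lte(diff(range(table(factor(b, levels = 1:5)))), 1)
  }
})

test_that("vocabulary is frequency-ranked, bijective, padding-free", {
  toks <- list(rep("A", 5), rep("B", 3), c("C", "REF"))
  v <- build_vocab(toks, max_vocab = 30000, reference_token = "REF")
  expect_equal(length(v$tokens), 4)
  expect_identical(v$tokens[1], "A")
  expect_identical(unname(v$index[v$tokens]), seq_along(v$tokens))
  expect_false(0 %in% v$index)

  # truncation keeps highest-frequency tokens and forces the reference in
  many <- lapply(1:50, function(i) rep(paste0("T", i), 51 - i))
  many <- c(many, list("REF"))
  v2 <- build_vocab(many, max_vocab = 21, reference_token = "REF")
  expect_equal(length(v2$tokens), 20)
  expect_true("REF" %in% v2$tokens)
  expect_true(all(paste0("T", 1:19) %in% v2$tokens))
})

test_that("sequence encoding round-trips tokens and recomputes elapsed time", {
  vt <- list(list(days_before = 10, tokens = c("A", "B")),
             list(days_before = 3, tokens = "ZZZ"),
             list(days_before = 0, tokens = "B"))
  v <- build_vocab(list(c("A", "B", "B")), reference_token = "A")
  enc <- encode_sample(vt, v)
  # middle visit is entirely out-of-vocabulary: omitted, gaps recomputed
  expect_length(enc$visits, 2)
  expect_equal(enc$elapsed, c(0, 10))
  decoded <- lapply(enc$visits, function(ix) seqrisk:::vocab_decode(v, ix))
  expect_identical(decoded, list(c("A", "B"), "B"))

  two <- encode_sample(list(list(days_before = 7, tokens = "A"),
                            list(days_before = 0, tokens = "B")), v)
  expect_equal(two$elapsed, c(0, 7))
})

test_that("round-trip encode/decode holds on random generated samples", {
  sim <- generate_cohort(sim_config(n_patients = 25, seed = 41))
  coh <- build_cohort(sim$timelines)
  enc <- encode_cohort(coh, sim$sdoh, sim$drug_map, min_lab_freq = 1)
  for (s in enc$samples[1:10]) {
    for (v in s$visits) {
      toks <- seqrisk:::vocab_decode(enc$vocab, v)
      expect_false(anyNA(toks))
      expect_identical(unname(enc$vocab$index[toks]), as.integer(v))
    }
    expect_equal(s$elapsed[1], 0)
    expect_true(all(s$elapsed >= 0))
  }
  expect_gt(enc$dropped_rx, 0)  # the unmapped drug is dropped and counted
})
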