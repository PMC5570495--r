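test_that("the m-of-n rule counts experiments with >= 2/3 units passing", {
  # three experiments with 3/3, 2/3, 1/3 units beyond mean + 3 SD
  vals <- list(c(141, 142, 143), c(141, 142, 120), c(141, 100, 100))
  call <- call_validated_hit(vals, 110, 10)
  expect_equal(call$n_experiments_pass, 2)
  expect_true(call$hit)

  call0 <- call_validated_hit(list(c(1, 2), c(1, 2), c(1, 2)), 110, 10)
  expect_equal(call0$n_experiments_pass, 0)
  expect_false(call0$hit)
})

test_that("strict vs inclusive comparison differ exactly at the threshold", {
  vals <- list(c(140, 140, 140))  # exactly mean + 3 SD
  expect_false(call_validated_hit(vals, 110, 10, comparison = "gt")$hit)
  expect_true(call_validated_hit(vals, 110, 10, comparison = "ge")$hit)
})

test_that("experiments with no units are excluded with a warning", {
  vals <- list(c(141, 142, 143), numeric(0), c(141, 142, 143))
  expect_warning(call <- call_validated_hit(vals, 110, 10), "no units")
  expect_equal(call$n_experiments, 2)
  expect_true(call$hit)
})

test_that("randomised small instances match the brute-force oracle", {
  set.seed(111)
  for (rep in 1:100) {
    n_exp <- sample(1:4, 1)
    vals <- lapply(seq_len(n_exp), function(e)
      rnorm(sample(1:4, 1), 125, 20))
    mu <- rnorm(n_exp, 110, 2)
    sd <- runif(n_exp, 5, 15)
    ge <- sample(c(TRUE, FALSE), 1)
    got <- call_validated_hit(vals, mu, sd,
                              comparison = if (ge) "ge" else "gt")
    want <- oracle_validated(vals, mu, sd, ge = ge)
    expect_equal(got$n_experiments_pass, want$n_pass)
    expect_equal(got$hit, want$hit)
  }
})

test_that("raising the SD multiplier never converts a miss into a hit", {
  set.seed(121)
  for (rep in 1:50) {
    vals <- lapply(1:3, function(e) rnorm(3, 125, 25))
    h3 <- call_validated_hit(vals, 110, 10, k = 3)$hit
    h4 <- call_validated_hit(vals, 110, 10, k = 4)$hit
    expect_true(h3 || !h4)
  }
})

test_that("fold of scrambled is a plain ratio with a guarded denominator", {
  expect_equal(fold_of_scrambled(220, 110), 2)
  expect_equal(fold_of_scrambled(110, 110), 1)
  expect_error(fold_of_scrambled(1, 0), "positive")
})

test_that("a caspase fold like the 1.8x positive control survives table I/O", {
  w <- tiny_wells(lib = lib_rows("CDK1", "si1", 150, 900))
  w$caspase <- c(1.0, 1.1, 0.9, 1.8) * 110
  path <- withr::local_tempfile(fileext = ".tsv")
  write_well_table(w, path)
  w2 <- read_well_table(path)
  scr_mean <- mean(w2$caspase[w2$role == "scrambled"])
  expect_equal(fold_of_scrambled(w2$caspase[w2$role == "library"], scr_mean),
               1.8)
})

test_that("proliferation classes reproduce the printed worked percentages", {
  expect_equal(as.character(proliferation_class(c(83, 149, 47, 24))),
               c("toxic", "cytostasis", "toxic", "toxic"))
})

test_that("proliferation boundaries partition [0, Inf) as documented", {
  expect_equal(as.character(proliferation_class(c(0, 99.9999, 100))),
               c("toxic", "toxic", "cytostasis"))
  expect_equal(as.character(proliferation_class(c(150, 150.0001, 1e6))),
               c("cytostasis", "growth", "growth"))
  # partition: every percentage maps to exactly one class
  grid <- seq(0, 400, by = 0.5)
  cls <- proliferation_class(grid)
  expect_false(anyNA(cls))
  expect_equal(nlevels(cls), 3)
  expect_error(classify_proliferation(-1), "non-negative")
  expect_error(classify_proliferation(100, 0), "positive")
  got <- classify_proliferation(4470, 3000)
  expect_equal(got$pct_of_seeding, 149)
  expect_equal(as.character(got$class), "cytostasis")
})

test_that("the 12 response combinations partition into exactly one class", {
  combos <- expand.grid(area = c(TRUE, FALSE), sab = c(TRUE, FALSE),
                        prolif = c("toxic", "cytostasis", "growth"),
                        stringsAsFactors = FALSE)
  cls <- classify_senescence_response(combos$area, combos$sab, combos$prolif)
  expect_equal(length(cls), 12)
  expect_false(anyNA(cls))
  complete <- combos$area & combos$sab & combos$prolif == "cytostasis"
  none <- !combos$area & !combos$sab & combos$prolif == "growth"
  expect_equal(cls == "complete", complete)
  expect_equal(cls == "none", none)
  expect_equal(cls == "partial", !complete & !none)
  # worked cases: full response, arrest failure, marker-free growth,
  # marker induction with toxicity
  expect_equal(as.character(classify_senescence_response(
    c(TRUE, TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE, TRUE),
    c("cytostasis", "growth", "growth", "toxic"))),
    c("complete", "partial", "none", "partial"))
  expect_error(classify_senescence_response(TRUE, TRUE, "odd"), "unknown")
})

test_that("cytokine hits flag induced cytokines and spare the rest", {
  shift <- c(cytokine_il6 = 5, cytokine_il8 = 5)
  cfg <- screen_config(
    profiles = effect_profile("ALDOA", shift, 130),
    n_null_genes = 1, seed = 131, plate_effect_sd = 0)
  w <- simulate_screen(cfg)
  st <- control_stats(w)
  calls <- call_cytokine_hits(w, st)
  aldoa <- calls[calls$gene == "ALDOA", ]
  expect_setequal(aldoa$marker[aldoa$hit],
                  c("cytokine_il6", "cytokine_il8"))
  null <- calls[calls$gene != "ALDOA", ]
  expect_equal(sum(null$hit), 0)
})

test_that("panel summary renders sorted gene lists and None rows", {
  resp <- data.frame(
    gene = c("ECT2", "ALDOA", "KIF11", "CIT", "ECT2", "ALDOA"),
    cell_line = c(rep("Parental", 4), rep("p21-/-", 2)),
    response = factor(c("complete", "complete", "partial", "none",
                        "partial", "partial"),
                      levels = c("complete", "partial", "none")))
  s <- summarize_panel(resp, panel = list(Parental = "wt", `p21-/-` = "p21 null"))
  expect_equal(s$senescence_response, c("ALDOA, ECT2", "None"))
  expect_equal(s$partial_senescence_response[1], "KIF11")
  expect_equal(s$genotype, c("wt", "p21 null"))
  expect_equal(s$unscored[2], "CIT, KIF11")
  # permuting input rows leaves the rendered lists unchanged
  s2 <- summarize_panel(resp[sample(nrow(resp)), ],
                        panel = list(Parental = "wt", `p21-/-` = "p21 null"))
  expect_equal(s, s2)
})
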