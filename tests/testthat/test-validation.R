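test_that("overlap is the ordered intersection, with self hits flagged separately", {
  ov <- compute_overlap(c("1", "2", "3"), c("9", "8"), "7")
  expect_length(ov$overlapping_ids, 0L)
  expect_false(ov$self_hit)

  ov2 <- compute_overlap(c("5", "2", "9", "7"), c("9", "2"), "7")
  expect_equal(ov2$overlapping_ids, c("2", "9"))   # result order preserved
  expect_true(ov2$self_hit)
})

test_that("the worked-example search result list overlaps six citations", {
  fx <- load_agr2_fixture()
  ov <- compute_overlap(fx$agr2_expression_results, fx$paper$cited_ids,
                        fx$paper$doc_id)
  expect_length(ov$overlapping_ids, 6L)
  expect_false(ov$self_hit)
  expect_length(fx$agr2_expression_results, 15L)
  expect_length(fx$paper$cited_ids, 46L)
})

test_that("CV classification distinguishes same/different authors and self hits", {
  pa <- list(author_name("Alpha", "A"), author_name("Bravo", "B"))
  expect_equal(classify_validation(character(), FALSE, pa), "NOT_CV")
  expect_equal(classify_validation(character(), TRUE, pa), "CV_S")
  expect_equal(
    classify_validation("c1", FALSE, pa,
                        list(c1 = list(author_name("Zed", "Z")))), "CV_D")
  expect_equal(
    classify_validation("c1", FALSE, pa,
                        list(c1 = list(author_name("Alpha", "A"),
                                       author_name("Zed", "Z")))), "CV_S")
  # different-author validation takes precedence in mixed cases
  expect_equal(
    classify_validation(c("c1", "c2"), FALSE, pa,
                        list(c1 = list(author_name("Alpha", "A")),
                             c2 = list(author_name("Zed", "Z")))), "CV_D")
  # missing author data is conservatively shared-author, with a warning
  expect_warning(
    cls <- classify_validation("c1", FALSE, pa, list()),
    "no author data")
  expect_equal(cls, "CV_S")
})

test_that("classification outcomes are mutually exclusive and exhaustive", {
  pa <- list(author_name("Alpha", "A"))
  others <- list(x = list(author_name("Zed", "Z")),
                 y = list(author_name("Alpha", "A")))
  set.seed(31)
  for (rep in 1:100) {
    ov <- sample(c(character(0), "x", "y"), sample(0:2, 1))
    self <- sample(c(TRUE, FALSE), 1)
    cls <- classify_validation(unique(ov), self, pa, others)
    expect_true(cls %in% c("NOT_CV", "CV_S", "CV_D"))
    expect_equal(cls == "NOT_CV", length(ov) == 0 && !self)
  }
})

test_that("the worked-example term set reproduces every printed D/S label", {
  fx <- load_agr2_fixture()
  rep <- evaluate_terms(fx$paper, fx$outcomes)
  cls <- vapply(rep$records, `[[`, character(1), "classification")
  expect_equal(unname(cls),
               ifelse(fx$expected$label == "D", "CV_D", "CV_S"))
  expect_equal(rep$n_cv_d_terms, 15L)
  expect_equal(rep$n_cv_s_terms, 1L)
  expect_equal(rep$unique_validating_citations, 17L)
  # D and S partition the validated terms
  expect_equal(rep$n_cv_d_terms + rep$n_cv_s_terms, rep$n_validated_terms)
  # per-term validating ids match the printed bracket lists
  for (i in seq_along(rep$records))
    expect_setequal(rep$records[[i]]$overlapping_ids,
                    setdiff(strsplit(fx$expected$validating_ids[i], ";")[[1]],
                            fx$paper$doc_id))
})

test_that("zero terms produce an all-zero report", {
  fx <- load_agr2_fixture()
  rep <- evaluate_terms(fx$paper, list())
  expect_equal(rep$n_terms, 0L)
  expect_equal(rep$n_cv_d_terms + rep$n_cv_s_terms +
                 rep$unique_validating_citations, 0L)
})

test_that("candidate-list evaluation handles planting, forcing, truncation", {
  fx <- load_agr2_fixture()
  # synthetic related-citations list with 4 planted cited ids
  rep <- evaluate_candidate_list(fx$paper, fx$related_citations)
  expect_equal(rep$unique_validating_citations, 4L)
  expect_equal(rep$n_cv_d_terms, 1L)

  # a list made of the paper's own citations is forcibly validated
  rep2 <- evaluate_candidate_list(fx$paper, fx$paper$cited_ids[1:20])
  expect_gt(rep2$n_validated_terms, 0L)

  rep3 <- evaluate_candidate_list(fx$paper, character())
  expect_equal(rep3$n_validated_terms, 0L)

  expect_warning(evaluate_candidate_list(fx$paper, as.character(1:30)),
                 "truncated")
})

test_that("summary aggregation computes percentages, CIs and sample SDs", {
  mk_rep <- function(id, d, s, u) {
    out <- search_outcome("t", character(), total_hits = 0)
    r <- evaluate_terms(document_record(id, title = "x"), list())
    r$n_cv_d_terms <- d; r$n_cv_s_terms <- s
    r$unique_validating_citations <- u
    r
  }
  all_d <- lapply(1:4, function(i) mk_rep(as.character(i), 2L, 0L, 2L))
  s1 <- aggregate_reports(all_d)
  expect_equal(s1$cv_d$pct, 100)
  expect_equal(s1$cv_d$ci_pct, c(100, 100))

  half <- list(mk_rep("1", 1L, 0L, 1L), mk_rep("2", 0L, 0L, 0L))
  expect_equal(aggregate_reports(half)$cv_d$pct, 50)

  # closed-form normal-approximation CI at the reference scale
  flags <- c(rep(1L, round(0.86 * 883)), rep(0L, 883 - round(0.86 * 883)))
  reps <- lapply(seq_along(flags), function(i)
    mk_rep(as.character(i), flags[i], 0L, flags[i]))
  s3 <- aggregate_reports(reps)
  p <- mean(flags)
  expect_equal(s3$cv_d$ci_pct[1],
               100 * (p - stats::qnorm(0.975) * sqrt(p * (1 - p) / 883)),
               tolerance = 1e-10)
  expect_equal(s3$cv_d$ci_pct[2],
               100 * (p + stats::qnorm(0.975) * sqrt(p * (1 - p) / 883)),
               tolerance = 1e-10)
  # realized proportion is 759/883: closed form gives [83.67%, 88.25%]
  expect_equal(round(s3$cv_d$ci_pct, 1), c(83.7, 88.2))
  # sample standard deviation, not population
  expect_equal(s3$sd_cv_d_terms, stats::sd(flags))
  expect_error(aggregate_reports(list()), "no reports")
})

test_that("the chance-validation null model matches its closed form and bounds", {
  expect_equal(as.numeric(random_cv_probability(0, 100)), 0)
  expect_equal(as.numeric(random_cv_probability(100, 100, k = 5)), 1)

  p <- random_cv_probability(100, 18e6, 20)
  expect_equal(as.numeric(p), 1 - (1 - 100 / 18e6)^20, tolerance = 1e-15)
  expect_equal(as.numeric(p), 1.11108e-4, tolerance = 1e-4)
  expect_equal(attr(p, "linear_approx"), 20 * 100 / 18e6)
  expect_error(random_cv_probability(101, 100), "C <= N")

  # monotone in C and k; linear approximation error bound
  Cs <- c(0, 10, 100, 1000)
  ps <- vapply(Cs, function(C) as.numeric(random_cv_probability(C, 1e5)), 1)
  expect_false(is.unsorted(ps))
  expect_lte(as.numeric(random_cv_probability(50, 1e5, 10)),
             as.numeric(random_cv_probability(50, 1e5, 20)))
  for (C in c(10, 200, 1000)) {
    kCN <- 20 * C / 1e5
    expect_lte(abs(as.numeric(random_cv_probability(C, 1e5, 20)) - kCN), kCN^2)
  }
})

test_that("report files round-trip and re-aggregate identically", {
  fx <- load_agr2_fixture()
  rep <- evaluate_terms(fx$paper, fx$outcomes)
  js <- tempfile(fileext = ".json"); cs <- tempfile(fileext = ".csv")
  write_paper_reports(list(rep), json_path = js, csv_path = cs)
  back <- read_paper_reports(js)
  expect_length(back, 1L)
  expect_identical(aggregate_reports(back), aggregate_reports(list(rep)))
  tab <- utils::read.csv(cs)
  expect_equal(tab$n_cv_d_terms, 15L)
})
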