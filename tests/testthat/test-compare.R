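make_results <- function(grades, assemblies, module_id = "M90001") {
  tibble::tibble(
    module_id = module_id, assembly_id = assemblies,
    blocks_total = 4L, blocks_present = 4L, steps_total = 4,
    steps_present = 4, category = "COMPLETE", grade = grades,
    step_graded = FALSE, loosely_complete = grades <= 2,
    strictly_complete = grades == 1)
}

test_that("completion rates are group fractions under either standard", {
  res <- make_results(c(1, 2, 2, 5), paste0("a", 1:4))
  expect_equal(completion_rate(res, loose = TRUE), 0.75)
  expect_equal(completion_rate(res, loose = FALSE), 0.25)
  expect_equal(completion_rate(make_results(rep(5, 3), paste0("a", 1:3))),
               0)
  expect_equal(completion_rate(make_results(rep(1, 3), paste0("a", 1:3))),
               1)
  expect_error(completion_rate(make_results(integer(0), character(0))),
               "empty group")
})

test_that("variability selection uses the population SD", {
  # closed forms: pop SD of {1,0} = 0.5; of {1,1,1,0.2} = 0.3464
  expect_equal(phycomet:::pop_sd(c(1, 0)), 0.5)
  expect_equal(phycomet:::pop_sd(c(1, 1, 1, 0.2)), sqrt(3) * 0.2,
               tolerance = 1e-12)
  expect_equal(phycomet:::pop_sd(c(1, 1, 1, 1)), 0)

  res <- rbind(
    make_results(c(1, 1, 5, 5), c("a1", "a2", "b1", "b2"), "M90001"),
    make_results(c(1, 1, 1, 1), c("a1", "a2", "b1", "b2"), "M90002"),
    make_results(c(5, 5, 5, 5), c("a1", "a2", "b1", "b2"), "M90003"))
  grp <- stats::setNames(c("A", "A", "B", "B"),
                         c("a1", "a2", "b1", "b2"))
  prof <- group_completion_profiles(res, grp)
  # M90003 is nowhere loosely complete -> ineligible
  expect_identical(sort(prof$module_id), c("M90001", "M90002"))
  expect_equal(prof$sd[prof$module_id == "M90001"], 0.5)
  expect_equal(prof$sd[prof$module_id == "M90002"], 0)

  sel <- variable_modules(prof, 0.2)
  expect_identical(sel$module_id, "M90001")
  expect_identical(variable_modules(prof, 0)$module_id,
                   c("M90001", "M90002"))
  expect_error(variable_modules(prof, 1.01), "\\[0, 1\\]")
  expect_error(group_completion_profiles(res, grp, sd_threshold = -0.1),
               "\\[0, 1\\]")
})

test_that("core module sets use inclusive prevalence and Venn regions sum", {
  res <- rbind(
    make_results(c(1, 1, 5, 5), paste0("a", 1:4), "M90001"),
    make_results(c(1, 1, 1, 1), paste0("a", 1:4), "M90002"),
    make_results(c(5, 5, 5, 5), paste0("a", 1:4), "M90003"),
    make_results(c(1, 1, 1, 1), paste0("b", 1:4), "M90001"),
    make_results(c(5, 5, 5, 5), paste0("b", 1:4), "M90002"),
    make_results(c(1, 5, 5, 5), paste0("b", 1:4), "M90003"))
  grp <- stats::setNames(rep(c("A", "B"), each = 4),
                         c(paste0("a", 1:4), paste0("b", 1:4)))
  cs <- core_module_sets(res, grp, prevalence = 0.5)
  # 2 of 4 complete meets the 50% boundary (inclusive)
  expect_true("M90001" %in% cs$sets$A)
  expect_false("M90003" %in% cs$sets$B)  # 1 of 4 < 0.5
  expect_identical(cs$sets$B, c("M90001"))
  expect_identical(sum(cs$regions$n),
                   length(unique(unlist(cs$sets))))
  expect_identical(cs$regions$n[cs$regions$region == "A&B"], 1L)
  expect_error(core_module_sets(res, grp, prevalence = 0), "\\(0, 1\\]")
  expect_error(core_module_sets(res, grp, prevalence = 1.2), "\\(0, 1\\]")
})

test_that("phi matches the closed form and the Pearson cross-check", {
  r <- presence_group_correlation(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(r$phi, 1)
  r <- presence_group_correlation(c(0, 0, 0, 1, 1), c(1, 1, 1, 0, 0))
  expect_equal(r$phi, -1)
  # n11=3, n10=1, n01=1, n00=3 -> phi = 8/16 = 0.5
  pres <- c(1, 1, 1, 0, 1, 0, 0, 0)
  ind <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(presence_group_correlation(pres, ind)$phi, 0.5)

  # two independent code paths agree to 1e-12
  set.seed(5150)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    p <- stats::rbinom(n, 1, 0.5)
    g <- stats::rbinom(n, 1, 0.5)
    r <- presence_group_correlation(p, g)
    if (r$undefined) {
      expect_true(stats::var(p) == 0 || stats::var(g) == 0)
    } else {
      expect_equal(r$phi, stats::cor(p, g), tolerance = 1e-12)
    }
  }

  # undefined on a zero margin, flagged rather than zeroed
  r <- presence_group_correlation(c(1, 1, 1), c(1, 0, 1))
  expect_true(r$undefined)
  expect_true(is.na(r$phi))
  expect_error(presence_group_correlation(c(1, 0), c(1, 0, 1)),
               "length")
  expect_error(presence_group_correlation(c(1, 2), c(1, 0)), "binary")
})

test_that("block presence matrix is consistent with grading", {
  cfg <- small_config()
  mods <- generate_modules(cfg)
  ann <- generate_annotations(mods, cfg)
  bm <- block_presence_matrix(mods, ann$annotations)
  res <- grade_matrix(mods, ann$annotations)
  expect_true(all(bm %in% 0:1))
  expect_identical(colnames(bm)[1], paste0(mods[[1]]$module_id, ".1"))
  # row sums per module equal blocks_present from completeness
  for (asm in rownames(bm)[1:4]) {
    for (mid in names(mods)[1:5]) {
      cols <- grep(paste0("^", mid, "\\."), colnames(bm))
      expect_identical(
        sum(bm[asm, cols]),
        res$blocks_present[res$assembly_id == asm &
                             res$module_id == mid])
    }
  }
  km <- ko_presence_matrix(ann$annotations, mods)
  expect_identical(sort(colnames(km)),
                   sort(unique(unlist(lapply(mods, ko_universe)))))
})

test_that("assembly order does not change comparison outputs", {
  cfg <- small_config()
  mods <- generate_modules(cfg)[1:8]
  ann <- generate_annotations(mods, cfg)
  res <- grade_matrix(mods, ann$annotations)
  perm <- sample(seq_along(ann$annotations))
  res_p <- grade_matrix(mods, ann$annotations[perm])
  p1 <- group_completion_profiles(res, ann$groups)
  p2 <- group_completion_profiles(res_p, ann$groups)
  expect_equal(p1, p2)
  c1 <- core_module_sets(res, ann$groups)
  c2 <- core_module_sets(res_p, ann$groups)
  expect_equal(c1, c2)
})

test_that("statistical helpers match hand-computed closed forms", {
  # Welch on {1,2,3} vs {2,4,6}: t = -2/sqrt(5/3), df = 50/17
  st <- stat_tests(c(1, 2, 3, 2, 4, 6), rep(c("a", "b"), each = 3))
  welch <- st[st$test == "welch_t", ]
  expect_equal(welch$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(welch$df1, 50 / 17, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  st0 <- stat_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  w0 <- st0[st0$test == "welch_t", ]
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  # internally constant groups: ANOVA F undefined -> degenerate flag
  stdeg <- stat_tests(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(all(stdeg$degenerate[stdeg$test %in%
                                     c("anova_F", "levene_W")]))
  expect_true(all(is.na(stdeg$statistic[stdeg$degenerate])))

  # three groups: ANOVA F equals the classic decomposition
  v <- c(1, 2, 3, 4, 2, 5, 6, 8, 1, 1, 2, 3)
  g <- rep(c("a", "b", "c"), each = 4)
  st3 <- stat_tests(v, g)
  fit <- stats::anova(stats::lm(v ~ g))
  expect_equal(st3$statistic[st3$test == "anova_F"], fit$`F value`[1],
               tolerance = 1e-12)
  expect_true(is.na(st3$statistic[st3$test == "welch_t"]))

  expect_error(stat_tests(1:4, rep("a", 4)), "two groups")
  expect_error(stat_tests(1:3, c("a", "a", "b")), "at least two")
})

test_that("long-format completion output is deterministic", {
  res <- rbind(make_results(c(1, 5), c("a1", "b1"), "M90002"),
               make_results(c(1, 1), c("a1", "b1"), "M90001"))
  grp <- stats::setNames(c("A", "B"), c("a1", "b1"))
  prof <- group_completion_profiles(res, grp)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_completion_long(prof, path)
  long <- utils::read.delim(path)
  expect_identical(long$module_id,
                   c("M90001", "M90001", "M90002", "M90002"))
  expect_identical(long$group, c("A", "B", "A", "B"))
  expect_equal(long$rate, c(1, 1, 1, 0))
})
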