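test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(p_core_present = 1.2))
  expect_error(synthetic_config(blocks_per_module = c(4, 2)))
  expect_error(synthetic_config(
    differential = data.frame(module = 1, group = "NotAClass",
                              knockout = 0.5)))
  expect_error(synthetic_config(seed = 2^33))
})

test_that("module generation honours structural probabilities", {
  base <- small_config()
  cfg0 <- synthetic_config(seed = 3, n_modules = 15, p_complex = 0,
                           p_or_alternative = 0, differential = NULL)
  mods0 <- generate_modules(cfg0)
  for (m in mods0) {
    expect_true(all(vapply(m$blocks, `[[`, "", "kind") == "atom"))
  }
  cfg1 <- synthetic_config(seed = 3, n_modules = 15, p_complex = 1,
                           p_or_alternative = 0, differential = NULL)
  mods1 <- generate_modules(cfg1)
  for (m in mods1) {
    expect_true(all(vapply(m$blocks, `[[`, "", "kind") == "and"))
  }
  # unique ids, unique KOs, all within the declared block range
  mods <- generate_modules(base)
  expect_false(anyDuplicated(names(mods)) > 0)
  all_kos <- unlist(lapply(mods, ko_universe))
  expect_false(anyDuplicated(all_kos) > 0)
  nb <- vapply(mods, function(m) length(m$blocks), integer(1))
  expect_true(all(nb >= base$blocks_per_module[1] &
                    nb <= base$blocks_per_module[2]))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 99)
  m1 <- generate_modules(cfg)
  m2 <- generate_modules(cfg)
  expect_identical(m1, m2)
  a1 <- generate_annotations(m1, cfg)
  a2 <- generate_annotations(m1, cfg)
  expect_identical(a1, a2)
  d1 <- generate_duplications(cfg)
  d2 <- generate_duplications(cfg)
  expect_identical(d1$records, d2$records)
  q1 <- generate_qc_fixtures(cfg)
  q2 <- generate_qc_fixtures(cfg)
  expect_identical(q1, q2)
  # byte-identical emitted fixture trees
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_study(dir1, cfg)
  simulate_study(dir2, cfg)
  files <- list.files(dir1, recursive = TRUE)
  expect_identical(files, list.files(dir2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f), warn = FALSE),
                     readLines(file.path(dir2, f), warn = FALSE),
                     label = f)
  }
})

test_that("annotation structure follows presence, knockout and dropout", {
  mods <- generate_modules(small_config())
  # saturation: everything present everywhere -> all grade 1
  cfg_all <- synthetic_config(
    seed = 5, n_modules = 20, p_core_present = 1, differential = NULL,
    groups = data.frame(label = c("A", "B"), n = 3L, source = "genome"))
  mods_all <- generate_modules(cfg_all)
  ann_all <- generate_annotations(mods_all, cfg_all)
  res <- grade_matrix(mods_all, ann_all$annotations)
  expect_true(all(res$grade == 1L))

  # certain knockout silences the module in the affected group
  cfg_ko <- synthetic_config(
    seed = 5, n_modules = 20, p_core_present = 1,
    differential = data.frame(module = 1, group = "A", knockout = 1),
    groups = data.frame(label = c("A", "B"), n = 4L, source = "genome"))
  mods_ko <- generate_modules(cfg_ko)
  ann_ko <- generate_annotations(mods_ko, cfg_ko)
  res_ko <- grade_matrix(mods_ko, ann_ko$annotations)
  m1 <- names(mods_ko)[1]
  in_a <- res_ko$module_id == m1 &
    startsWith(res_ko$assembly_id, "A_")
  expect_true(all(res_ko$grade[in_a] == 5L))
  prof <- group_completion_profiles(res_ko, ann_ko$groups)
  expect_equal(prof$rate_A[prof$module_id == m1], 0)

  # transcriptome dropout thins KO content by roughly its rate
  cfg_dr <- synthetic_config(
    seed = 5, n_modules = 50, p_core_present = 1, differential = NULL,
    dropout_1kp = 0.3,
    groups = data.frame(label = c("G", "TK"), n = 6L,
                        source = c("genome", "1KP")))
  mods_dr <- generate_modules(cfg_dr)
  ann_dr <- generate_annotations(mods_dr, cfg_dr)
  n_genome <- mean(lengths(lapply(
    ann_dr$annotations[startsWith(names(ann_dr$annotations), "G_")],
    `[[`, "kos")))
  n_1kp <- mean(lengths(lapply(
    ann_dr$annotations[startsWith(names(ann_dr$annotations), "TK_")],
    `[[`, "kos")))
  expect_equal(n_1kp / n_genome, 0.7, tolerance = 0.05)
})

test_that("a KO planted in exactly one group gives phi of one", {
  cfg <- small_config()
  mods <- generate_modules(cfg)
  ann <- generate_annotations(mods, cfg)
  planted <- "K09999"
  target <- names(ann$groups)[ann$groups == "Bangiophyceae"]
  ann$annotations <- lapply(ann$annotations, function(a) {
    if (a$assembly_id %in% target) {
      annotation_set(a$assembly_id, c(a$kos, planted))
    } else {
      a
    }
  })
  km <- ko_presence_matrix(ann$annotations)
  ind <- as.integer(ann$groups[rownames(km)] == "Bangiophyceae")
  expect_equal(presence_group_correlation(km[, planted], ind)$phi, 1)
})

test_that("uniform supports put about half the events past the filter", {
  cfg <- synthetic_config(
    seed = 17,
    duplication = list(n_tips = 12L, events_per_node = c(8L, 16L),
                       n_categories = 10L, enrichment_odds = 8,
                       p_unannotated = 0.1))
  dup <- generate_duplications(cfg)
  n <- nrow(dup$records)
  kept <- nrow(filter_support(dup$records, 0.5))
  # binomial(n, 1/2) within 4 standard deviations
  expect_lt(abs(kept - n / 2), 4 * sqrt(n / 4))
  # fixed event count per node before filtering
  cfg5 <- synthetic_config(
    seed = 17,
    duplication = list(n_tips = 6L, events_per_node = c(5L, 5L),
                       n_categories = 5L, enrichment_odds = 8,
                       p_unannotated = 0))
  dup5 <- generate_duplications(cfg5)
  expect_true(all(node_totals(dup5$records, dup5$tree) == 5L))
})

test_that("planted enrichment makes the enriched category modal", {
  cfg <- synthetic_config(
    seed = 23,
    duplication = list(n_tips = 10L, events_per_node = c(10L, 15L),
                       n_categories = 8L, enrichment_odds = 8,
                       p_unannotated = 0.05))
  dup <- generate_duplications(cfg)
  s <- integrate_annotations(dup$records, dup$gene_categories)
  hits <- vapply(s$nodes$node, function(nd) {
    sub <- s$categories[s$categories$node == nd, ]
    modal <- sub$category_id[which.max(sub$gene_count)]
    identical(modal, unname(dup$enriched[nd]))
  }, logical(1))
  expect_true(all(hits))
})

test_that("simulate_study emits a complete, reloadable fixture set", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  simulate_study(dir, cfg)
  expect_true(all(file.exists(file.path(
    dir, c("modules.tsv", "metadata.tsv", "Duplications.tsv", "tree.nwk",
           "gene_annotations.tsv", "config.yaml")))))
  mods <- read_module_table(file.path(dir, "modules.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"))
  anns <- lapply(meta$assembly_id, function(a) {
    read_ko_annotations(file.path(dir, "annotations", paste0(a, ".tsv")), a)
  })
  res <- grade_matrix(mods, anns)
  expect_identical(nrow(res), length(mods) * nrow(meta))
  tree <- read_species_tree(file.path(dir, "tree.nwk"))
  recs <- read_duplications(file.path(dir, "Duplications.tsv"))
  tot <- node_totals(filter_support(recs, 0.5), tree)
  expect_identical(sum(tot), nrow(filter_support(recs, 0.5)))
  cats <- read_gene_categories(file.path(dir, "gene_annotations.tsv"))
  expect_true(all(c("gene_id", "category_id") %in% names(cats)))
})
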