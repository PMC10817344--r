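# Class-level comparison of module completion: per-group completion
# rates, cross-group variability selection, core-module Venn regions,
# presence/absence-taxon association and the study's statistical helpers.

check_groups <- function(results, groups) {
  stopifnot(is.character(groups) || is.factor(groups))
  groups <- stats::setNames(as.character(groups), names(groups))
  asm <- unique(results$assembly_id)
  missing <- setdiff(asm, names(groups))
  if (length(missing)) {
    stop("no group assignment for assembly: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups[asm]
}

#' Completion rate of one module in one group
#'
#' Fraction of the group's assemblies in which the module is loosely
#' (grade <= 2) or strictly (grade 1) complete.
#'
#' @param results Rows of a [grade_matrix()] tibble for one module and
#'   the assemblies of one group.
#' @param loose Use the loose standard (default) or the strict one.
#' @return Rate in `[0, 1]`.
#' @export
completion_rate <- function(results, loose = TRUE) {
  if (nrow(results) == 0) stop("empty group", call. = FALSE)
  flag <- if (loose) results$loosely_complete else results$strictly_complete
  mean(flag)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-group completion profiles with cross-group variability
#'
#' For every eligible module, the completion rate in each group and the
#' population standard deviation (n denominator) of those rates. Only
#' modules loosely complete in at least one assembly overall are
#' eligible. Modules whose rate SD meets `sd_threshold` are flagged
#' variable.
#'
#' @param results Tibble from [grade_matrix()].
#' @param groups Named character vector: assembly id -> group label
#'   (taxonomic class, order, or transcriptome source). At least two
#'   groups are required.
#' @param loose Completion standard passed to [completion_rate()].
#' @param sd_threshold Variability cutoff on the population SD, in
#'   `[0, 1]`.
#' @return Tibble with `module_id`, one `rate_<group>` column per group,
#'   `sd` and `variable`, sorted by SD descending then module id.
#' @export
group_completion_profiles <- function(results, groups, loose = TRUE,
                                      sd_threshold = 0.2) {
  if (sd_threshold < 0 || sd_threshold > 1) {
    stop("sd_threshold must be in [0, 1]", call. = FALSE)
  }
  grp <- check_groups(results, groups)
  labels <- sort(unique(grp))
  if (length(labels) < 2) stop("need at least two groups", call. = FALSE)
  eligible <- unique(results$module_id[results$loosely_complete])
  asm_group <- grp[unique(results$assembly_id)]
  rows <- lapply(sort(eligible), function(mid) {
    sub <- results[results$module_id == mid, ]
    rates <- vapply(labels, function(g) {
      completion_rate(sub[grp[sub$assembly_id] == g, , drop = FALSE],
                      loose = loose)
    }, numeric(1))
    out <- c(list(module_id = mid),
             as.list(stats::setNames(rates, paste0("rate_", labels))),
             list(sd = pop_sd(rates)))
    tibble::as_tibble(out)
  })
  prof <- do.call(rbind, rows)
  prof$variable <- prof$sd >= sd_threshold
  prof[order(-prof$sd, prof$module_id), ]
}

#' Select variable modules by cross-group SD
#'
#' Modules whose per-group completion rates have a population standard
#' deviation at or above the threshold (0.2 by default), sorted by SD
#' descending then module id.
#'
#' @param profiles Tibble from [group_completion_profiles()] (must carry
#'   `module_id` and `sd`).
#' @param sd_threshold Cutoff in `[0, 1]`.
#' @return Tibble of selected rows.
#' @export
variable_modules <- function(profiles, sd_threshold = 0.2) {
  if (sd_threshold < 0 || sd_threshold > 1) {
    stop("sd_threshold must be in [0, 1]", call. = FALSE)
  }
  sel <- profiles[profiles$sd >= sd_threshold, ]
  sel[order(-sel$sd, sel$module_id), ]
}

#' Core module sets per group and their Venn decomposition
#'
#' A module belongs to a group's core set when it is loosely complete in
#' at least `prevalence` of that group's assemblies (inclusive at the
#' boundary). Returns the per-group sets and the cardinality of every
#' region of the k-set Venn decomposition.
#'
#' @param results Tibble from [grade_matrix()] (genome-source assemblies
#'   only, by the study design).
#' @param groups Named character vector assembly id -> group label.
#' @param prevalence Fraction in `(0, 1]`.
#' @param loose Completion standard.
#' @return List with `sets` (named list of module-id vectors) and
#'   `regions` (tibble `region`, `n`: `region` is the `&`-joined sorted
#'   group labels of the exact membership pattern).
#' @export
core_module_sets <- function(results, groups, prevalence = 0.5,
                             loose = TRUE) {
  if (prevalence <= 0 || prevalence > 1) {
    stop("prevalence must be in (0, 1]", call. = FALSE)
  }
  grp <- check_groups(results, groups)
  labels <- sort(unique(grp))
  sets <- lapply(labels, function(g) {
    sub <- results[grp[results$assembly_id] == g, ]
    mids <- sort(unique(sub$module_id))
    keep <- vapply(mids, function(mid) {
      completion_rate(sub[sub$module_id == mid, , drop = FALSE],
                      loose = loose) >= prevalence
    }, logical(1))
    mids[keep]
  })
  names(sets) <- labels
  universe <- sort(unique(unlist(sets)))
  pattern <- vapply(universe, function(mid) {
    paste(labels[vapply(sets, function(s) mid %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(pattern)
  regions <- tibble::tibble(region = names(tab), n = as.integer(tab))
  list(sets = sets, regions = regions[order(regions$region), ])
}

#' Phi association between binary presence and a binary grouping
#'
#' The phi coefficient of the 2x2 contingency table,
#' `(n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)` — equal to the
#' Pearson correlation of the two 0/1 vectors. +1 means the feature is
#' present in exactly the indicated group's assemblies and absent from
#' the rest; -1 the complementary pattern. When either vector has zero
#' variance (a zero table margin) the coefficient is undefined and
#' flagged rather than forced to 0.
#'
#' @param presence 0/1 (or logical) vector over assemblies: feature (KO
#'   or block) presence.
#' @param indicator 0/1 (or logical) vector of the same length: group
#'   membership.
#' @return List with `phi` (numeric or `NA`), `undefined` flag and the
#'   2x2 `table`.
#' @export
#' @examples
#' presence_group_correlation(c(1, 1, 0, 0), c(1, 1, 0, 0))$phi  # +1
presence_group_correlation <- function(presence, indicator) {
  presence <- as.integer(presence)
  indicator <- as.integer(indicator)
  if (length(presence) != length(indicator)) {
    stop("presence and indicator differ in length", call. = FALSE)
  }
  if (length(presence) < 2) stop("need at least two assemblies",
                                 call. = FALSE)
  if (!all(presence %in% 0:1) || !all(indicator %in% 0:1)) {
    stop("vectors must be binary 0/1", call. = FALSE)
  }
  n11 <- sum(presence == 1 & indicator == 1)
  n10 <- sum(presence == 1 & indicator == 0)
  n01 <- sum(presence == 0 & indicator == 1)
  n00 <- sum(presence == 0 & indicator == 0)
  tab <- matrix(c(n11, n10, n01, n00), 2, 2,
                dimnames = list(presence = c("1", "0"),
                                indicator = c("1", "0")))
  denom <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  if (denom == 0) {
    return(list(phi = NA_real_, undefined = TRUE, table = tab))
  }
  list(phi = (n11 * n00 - n10 * n01) / sqrt(denom), undefined = FALSE,
       table = tab)
}

#' Phi of every feature column against a group indicator
#'
#' @param presence_matrix Binary matrix, assemblies as rows, features
#'   (KOs or blocks) as columns.
#' @param indicator Binary group-membership vector over the rows.
#' @return Tibble `feature`, `phi`, `undefined`, sorted by feature.
#' @export
feature_group_correlations <- function(presence_matrix, indicator) {
  feats <- colnames(presence_matrix)
  rows <- lapply(feats, function(f) {
    r <- presence_group_correlation(presence_matrix[, f], indicator)
    tibble::tibble(feature = f, phi = r$phi, undefined = r$undefined)
  })
  out <- do.call(rbind, rows)
  out[order(out$feature), ]
}

#' Assemblies-by-blocks presence matrix
#'
#' Entry 1 when the block's expression is satisfied by the assembly's
#' KO set. Columns are `module_id.block_index` (1-based, definition
#' order).
#'
#' @param modules List of `module_definition` objects.
#' @param annotations List of `annotation_set` objects.
#' @return Binary integer matrix.
#' @export
block_presence_matrix <- function(modules, annotations) {
  ids <- vapply(annotations, function(a) a$assembly_id, character(1))
  cols <- unlist(lapply(modules, function(m) {
    paste0(m$module_id, ".", seq_along(m$blocks))
  }), use.names = FALSE)
  mat <- matrix(0L, length(ids), length(cols),
                dimnames = list(ids, cols))
  for (a in annotations) {
    j <- 0L
    for (m in modules) {
      for (b in m$blocks) {
        j <- j + 1L
        mat[a$assembly_id, j] <- as.integer(satisfied(b, a$kos))
      }
    }
  }
  mat
}

#' Assemblies-by-KO presence matrix
#'
#' Entry 1 when the KO is annotated in the assembly. Columns are the
#' union of the modules' required orthologue universes (or all annotated
#' KOs when `modules` is `NULL`).
#'
#' @param annotations List of `annotation_set` objects.
#' @param modules Optional list of `module_definition` objects
#'   restricting the KO universe.
#' @return Binary integer matrix.
#' @export
ko_presence_matrix <- function(annotations, modules = NULL) {
  ids <- vapply(annotations, function(a) a$assembly_id, character(1))
  kos <- if (is.null(modules)) {
    sort(unique(unlist(lapply(annotations, function(a) a$kos))))
  } else {
    sort(unique(unlist(lapply(modules, ko_universe))))
  }
  mat <- matrix(0L, length(ids), length(kos), dimnames = list(ids, kos))
  for (a in annotations) {
    mat[a$assembly_id, ] <- as.integer(kos %in% a$kos)
  }
  mat
}

#' Study statistical helpers
#'
#' Two-tailed Welch t test assuming unequal variances (two groups only),
#' single-factor ANOVA, and Levene's test for homogeneity of variance
#' centred on the group mean. When every group is internally constant
#' the ANOVA F statistic is undefined (zero within-group sum of
#' squares); such rows carry `degenerate = TRUE` instead of a value.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation; at least two groups with
#'   at least two observations each.
#' @return Tibble with one row per test: `test` (`welch_t`, `anova_F`,
#'   `levene_W`), `statistic`, `df1`, `df2`, `p_value`, `degenerate`.
#' @export
stat_tests <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  within_var <- tapply(values, groups, stats::var)
  degenerate <- all(within_var == 0)

  rows <- list()
  if (nlevels(groups) == 2) {
    if (degenerate) {
      rows$welch <- tibble::tibble(test = "welch_t", statistic = NA_real_,
                                   df1 = NA_real_, df2 = NA_real_,
                                   p_value = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(values ~ groups, var.equal = FALSE)
      rows$welch <- tibble::tibble(test = "welch_t",
                                   statistic = unname(tt$statistic),
                                   df1 = unname(tt$parameter),
                                   df2 = NA_real_,
                                   p_value = tt$p.value,
                                   degenerate = FALSE)
    }
  } else {
    rows$welch <- tibble::tibble(test = "welch_t", statistic = NA_real_,
                                 df1 = NA_real_, df2 = NA_real_,
                                 p_value = NA_real_, degenerate = FALSE)
  }
  if (degenerate) {
    rows$anova <- tibble::tibble(test = "anova_F", statistic = NA_real_,
                                 df1 = NA_real_, df2 = NA_real_,
                                 p_value = NA_real_, degenerate = TRUE)
    rows$levene <- tibble::tibble(test = "levene_W", statistic = NA_real_,
                                  df1 = NA_real_, df2 = NA_real_,
                                  p_value = NA_real_, degenerate = TRUE)
  } else {
    ao <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    rows$anova <- tibble::tibble(test = "anova_F",
                                 statistic = unname(ao$statistic),
                                 df1 = unname(ao$parameter[1]),
                                 df2 = unname(ao$parameter[2]),
                                 p_value = ao$p.value, degenerate = FALSE)
    lv <- car::leveneTest(values ~ groups, center = mean)
    rows$levene <- tibble::tibble(test = "levene_W",
                                  statistic = lv[1, "F value"],
                                  df1 = lv[1, "Df"], df2 = lv[2, "Df"],
                                  p_value = lv[1, "Pr(>F)"],
                                  degenerate = FALSE)
  }
  do.call(rbind, rows)
}

#' Write completion profiles in long format
#'
#' TSV `module_id, group, rate` with deterministic ordering (module then
#' group).
#'
#' @param profiles Tibble from [group_completion_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_completion_long <- function(profiles, path) {
  rate_cols <- grep("^rate_", names(profiles), value = TRUE)
  long <- do.call(rbind, lapply(rate_cols, function(cl) {
    data.frame(module_id = profiles$module_id,
               group = sub("^rate_", "", cl),
               rate = profiles[[cl]], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$module_id, long$group), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
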