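# Per-assembly module completeness grading.
#
# Block-based categories follow the reconstruction semantics of KEGG
# Mapper: a block is present only when its boolean expression is
# satisfied (every subunit of a complex must be annotated).  Modules
# whose only deficit is a partially annotated complex are re-graded on
# KO "steps", each missing step counting as one missing block.

CATEGORY_LEVELS <- c("COMPLETE", "MISSING_1", "MISSING_2", "INCOMPLETE",
                     "ABSENT")

category_from_missing <- function(n_present, n_missing) {
  if (n_present == 0) return("ABSENT")
  if (n_missing == 0) return("COMPLETE")
  if (n_missing == 1) return("MISSING_1")
  if (n_missing == 2) return("MISSING_2")
  "INCOMPLETE"
}

grade_of <- function(category) match(category, CATEGORY_LEVELS)

#' Construct an annotation set
#'
#' Holds the KO content of one assembly. When a gene-to-KO mapping is
#' given, `kos` is derived from it.
#'
#' @param assembly_id Assembly identifier (unique per study).
#' @param kos Character vector of KO ids (deduplicated, case-normalised).
#' @param gene_to_ko Optional data frame with columns `gene_id`, `ko`.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(assembly_id, kos = character(0),
                           gene_to_ko = NULL) {
  if (!is.null(gene_to_ko)) {
    stopifnot(all(c("gene_id", "ko") %in% names(gene_to_ko)))
    kos <- gene_to_ko$ko
  }
  kos <- normalise_ko(kos)
  bad <- kos[!is_ko_id(kos)]
  if (length(bad)) {
    stop("invalid KO id(s) in annotation for '", assembly_id, "': ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  structure(list(assembly_id = assembly_id, kos = sort(unique(kos)),
                 gene_to_ko = gene_to_ko),
            class = "annotation_set")
}

#' Read a KO annotation table
#'
#' TSV with one row per gene-KO link: `gene_id<TAB>KO`; multiple KOs per
#' gene are allowed (one row each). A header row `gene_id\tko` is
#' detected and skipped.
#'
#' @param path File path.
#' @param assembly_id Assembly id to attach; defaults to the file name
#'   without extension.
#' @return An `annotation_set`.
#' @export
read_ko_annotations <- function(path,
                                assembly_id = sub("\\.[^.]*$", "",
                                                  basename(path))) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "ko"))
  if (nrow(tab) && tolower(tab$ko[1]) %in% c("ko", "ko_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  annotation_set(assembly_id, gene_to_ko = tab)
}

# ---- block satisfaction -------------------------------------------------

#' Evaluate a block expression against a KO set
#'
#' An atom is satisfied when its KO is annotated (optional atoms are
#' always satisfied); an AND node requires all children — every subunit
#' of a complex must be present for the block to count as present; an OR
#' node requires any child.
#'
#' @param expr Expression tree (a `ko_expr`, e.g. one element of
#'   `module$blocks`).
#' @param kos Character vector of annotated KO ids.
#' @return Logical flag.
#' @export
satisfied <- function(expr, kos) {
  switch(expr$kind,
    atom = isTRUE(expr$optional) || (expr$ko %in% kos),
    and  = all(vapply(expr$children, satisfied, logical(1), kos = kos)),
    or   = any(vapply(expr$children, satisfied, logical(1), kos = kos))
  )
}

# ---- step credit --------------------------------------------------------

# All minimal KO sets satisfying `expr` (optional atoms contribute
# nothing). OR enumerates alternatives, AND takes unions across children.
minimal_sets <- function(expr) {
  switch(expr$kind,
    atom = if (isTRUE(expr$optional)) list(character(0)) else list(expr$ko),
    or   = unique(do.call(c, lapply(expr$children, minimal_sets))),
    and  = {
      sets <- list(character(0))
      for (ch in expr$children) {
        chs <- minimal_sets(ch)
        sets <- unlist(lapply(sets, function(s) {
          lapply(chs, function(t) sort(unique(c(s, t))))
        }), recursive = FALSE)
        sets <- unique(sets)
        if (length(sets) > 10000) {
          stop("block has too many alternative satisfying sets",
               call. = FALSE)
        }
      }
      sets
    }
  )
}

n_required_atoms <- function(expr) length(collect_kos(expr))

#' KO-step credit of one block
#'
#' Among all minimal satisfying KO sets of the block's boolean
#' expression, selects the alternative maximising the fraction of steps
#' present (ties broken by fewer total steps, then by the
#' lexicographically smallest KO list) and returns its step counts.
#' Optional components carry no steps.
#'
#' @param block Expression tree for one block.
#' @param kos Character vector of annotated KO ids.
#' @return Named numeric vector `c(steps_present, steps_total)`.
#' @export
#' @examples
#' b <- parse_definition("K00001+K00002+K00003", "M")$blocks[[1]]
#' step_credit(b, c("K00001", "K00002"))  # 2 of 3
step_credit <- function(block, kos) {
  if (n_required_atoms(block) > 64) {
    stop("refusing step enumeration: block has more than 64 required ",
         "orthologues", call. = FALSE)
  }
  sets <- minimal_sets(block)
  total <- lengths(sets)
  present <- vapply(sets, function(s) sum(s %in% kos), numeric(1))
  frac <- ifelse(total == 0, 1, present / pmax(total, 1))
  key <- vapply(sets, paste, character(1), collapse = ",")
  best <- order(-frac, total, key)[1]
  c(steps_present = present[best], steps_total = total[best])
}

# ---- module grading -----------------------------------------------------

#' Grade one module against one assembly
#'
#' Block-based category from the number of missing blocks: 0 missing is
#' complete (grade 1); 1 or 2 missing grade 2 or 3; three or more missing
#' with at least one block present is incomplete (grade 4); no block
#' present is absent (grade 5). When any block is partially satisfied
#' through a multi-KO complex (step fraction strictly between 0 and 1), a
#' step-based category is computed from the summed [step_credit()] counts
#' — each missing KO step counting as one missing block — and the final
#' category is the better (numerically lower) of the two. A module is
#' only finally absent when the assembly carries none of the module's
#' required orthologues.
#'
#' @param module A `module_definition`.
#' @param ann An `annotation_set` (or plain character vector of KO ids).
#' @return A `completeness_result`: list with `module_id`, `assembly_id`,
#'   `blocks_total`, `blocks_present`, `steps_total`, `steps_present`,
#'   `category`, `grade` (1-5), `step_graded`, `loosely_complete`
#'   (grade <= 2) and `strictly_complete` (grade == 1).
#' @export
#' @examples
#' m <- parse_definition("K00001+K00002+K00003", "M00001")
#' r <- grade_module(m, annotation_set("asm1", c("K00001", "K00002")))
#' r$grade  # partial complex: one step missing -> grade 2
grade_module <- function(module, ann) {
  stopifnot(inherits(module, "module_definition"))
  if (is.character(ann)) ann <- annotation_set("", ann)
  stopifnot(inherits(ann, "annotation_set"))
  if (length(module$blocks) == 0) {
    stop("module '", module$module_id, "' has zero blocks", call. = FALSE)
  }
  kos <- ann$kos
  sat <- vapply(module$blocks, satisfied, logical(1), kos = kos)
  blocks_total <- length(sat)
  blocks_present <- sum(sat)

  credits <- vapply(module$blocks, step_credit, numeric(2), kos = kos)
  steps_present <- sum(credits["steps_present", ])
  steps_total <- sum(credits["steps_total", ])
  frac <- ifelse(credits["steps_total", ] == 0, 1,
                 credits["steps_present", ] / pmax(credits["steps_total", ], 1))
  partial <- any(frac > 0 & frac < 1)

  block_cat <- category_from_missing(blocks_present,
                                     blocks_total - blocks_present)
  final_cat <- block_cat
  step_graded <- FALSE
  if (partial) {
    step_cat <- category_from_missing(steps_present,
                                      steps_total - steps_present)
    if (grade_of(step_cat) < grade_of(final_cat)) {
      final_cat <- step_cat
      step_graded <- TRUE
    }
  }
  # absent means truly no signal: no required orthologue annotated at all
  if (length(intersect(ko_universe(module), kos)) == 0) {
    final_cat <- "ABSENT"
    step_graded <- FALSE
  }
  grade <- grade_of(final_cat)
  structure(list(
    module_id = module$module_id,
    assembly_id = ann$assembly_id,
    blocks_total = blocks_total,
    blocks_present = blocks_present,
    steps_total = as.numeric(steps_total),
    steps_present = as.numeric(steps_present),
    category = final_cat,
    grade = grade,
    step_graded = step_graded,
    loosely_complete = grade <= 2,
    strictly_complete = grade == 1
  ), class = "completeness_result")
}

#' Grade all modules against all assemblies
#'
#' @param modules List of `module_definition` objects.
#' @param annotations List of `annotation_set` objects with unique
#'   assembly ids.
#' @return Tibble with one row per (assembly, module) holding all
#'   [grade_module()] fields.
#' @export
grade_matrix <- function(modules, annotations) {
  ids <- vapply(annotations, function(a) a$assembly_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate assembly ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (ann in annotations) {
    for (m in modules) {
      r <- grade_module(m, ann)
      rows[[length(rows) + 1L]] <- tibble::as_tibble(unclass(r))
    }
  }
  do.call(rbind, rows)
}

#' Per-assembly completeness summary
#'
#' Counts of strictly and loosely complete modules per assembly,
#' mirroring per-assembly complete-pathway totals.
#'
#' @param results Tibble from [grade_matrix()].
#' @return Tibble with `assembly_id`, `n_strict`, `n_loose`.
#' @export
completeness_summary <- function(results) {
  ids <- unique(results$assembly_id)
  tibble::tibble(
    assembly_id = ids,
    n_strict = vapply(ids, function(a) {
      sum(results$strictly_complete[results$assembly_id == a])
    }, numeric(1)),
    n_loose = vapply(ids, function(a) {
      sum(results$loosely_complete[results$assembly_id == a])
    }, numeric(1))
  )
}

#' Wide integer grade matrix
#'
#' @param results Tibble from [grade_matrix()].
#' @return Integer matrix, assemblies as rows, modules as columns.
#' @export
grades_wide <- function(results) {
  asm <- unique(results$assembly_id)
  mod <- unique(results$module_id)
  m <- matrix(NA_integer_, length(asm), length(mod),
              dimnames = list(asm, mod))
  m[cbind(match(results$assembly_id, asm), match(results$module_id, mod))] <-
    as.integer(results$grade)
  m
}

#' Write the grade matrix as TSV
#'
#' Assemblies as rows, modules as columns, integer grades 1-5.
#'
#' @param results Tibble from [grade_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grade_matrix <- function(results, path) {
  m <- grades_wide(results)
  df <- data.frame(assembly_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
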