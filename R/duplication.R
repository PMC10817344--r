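# Gene-duplication events on a species tree: OrthoFinder-dialect
# Duplications.tsv parsing, support filtering, per-node totals and
# functional-category integration.

DUP_COLUMNS <- c("Orthogroup", "Species Tree Node", "Gene Tree Node",
                 "Support", "Type", "Genes 1", "Genes 2")

#' Read an OrthoFinder-dialect duplications table
#'
#' Tab-separated with header `Orthogroup, Species Tree Node, Gene Tree
#' Node, Support, Type, Genes 1, Genes 2`; the two gene lists are
#' comma-separated.
#'
#' @param path File path.
#' @return Tibble with columns `orthogroup`, `node`, `gene_tree_node`,
#'   `support` (numeric in `[0, 1]`), `type`, and list-columns
#'   `genes_1`, `genes_2`.
#' @export
read_duplications <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(DUP_COLUMNS, names(tab))
  if (length(missing)) {
    stop("duplications table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    warning("empty duplications table: ", path, call. = FALSE)
  }
  support <- suppressWarnings(as.numeric(tab$Support))
  if (nrow(tab) && anyNA(support)) {
    stop("non-numeric Support value(s): ",
         paste(utils::head(tab$Support[is.na(support)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(support < 0 | support > 1, na.rm = TRUE)) {
    stop("Support values outside [0, 1]", call. = FALSE)
  }
  split_genes <- function(x) {
    lapply(strsplit(x, ","), function(g) {
      g <- trimws(g)
      g[nzchar(g)]
    })
  }
  tibble::tibble(
    orthogroup = tab$Orthogroup,
    node = tab[["Species Tree Node"]],
    gene_tree_node = tab[["Gene Tree Node"]],
    support = support,
    type = tab$Type,
    genes_1 = split_genes(tab[["Genes 1"]]),
    genes_2 = split_genes(tab[["Genes 2"]])
  )
}

#' Filter duplication events by support
#'
#' Keeps events whose support is at least `min_support` (inclusive
#' boundary: an event at exactly the threshold is retained).
#'
#' @param records Tibble from [read_duplications()].
#' @param min_support Threshold in `[0, 1]`; default 0.5.
#' @return Filtered tibble.
#' @export
filter_support <- function(records, min_support = 0.5) {
  if (min_support < 0 || min_support > 1) {
    stop("min_support must be in [0, 1]", call. = FALSE)
  }
  records[records$support >= min_support, ]
}

#' Read a species tree with labelled internal nodes
#'
#' Newick file; tips are assembly ids, internal node labels (e.g. `N1`)
#' must be unique.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs)) {
    stop("species tree node labels are not unique", call. = FALSE)
  }
  tree
}

#' Duplication event totals per species-tree node
#'
#' Counts events (table rows) per node. With a tree supplied, every tree
#' node (tips and internal) appears in the result, zero-filled, and
#' records naming unknown nodes are an error.
#'
#' @param records Tibble of (filtered) duplication records.
#' @param tree Optional `phylo` species tree.
#' @return Named integer vector node -> event count.
#' @export
node_totals <- function(records, tree = NULL) {
  counts <- table(records$node)
  if (is.null(tree)) {
    return(stats::setNames(as.integer(counts), names(counts)))
  }
  labs <- c(tree$tip.label, tree$node.label)
  unknown <- setdiff(names(counts), labs)
  if (length(unknown)) {
    stop("duplication records name unknown tree node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(integer(length(labs)), labs)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Read a gene functional-annotation table
#'
#' TSV `gene_id<TAB>namespace<TAB>category_id<TAB>category_name` (the
#' namespace distinguishes e.g. InterPro Homologous Superfamily entries
#' from GO terms; no ontology traversal is performed).
#'
#' @param path File path.
#' @return Tibble with those four columns.
#' @export
read_gene_categories <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "namespace",
                                         "category_id", "category_name"))
  if (nrow(tab) && tab$gene_id[1] == "gene_id") tab <- tab[-1, ]
  tibble::as_tibble(tab)
}

#' Integrate duplicated genes with functional categories per node
#'
#' For each species-tree node, the duplicated gene set is the union of
#' both descendant gene lists across the node's records (a gene
#' appearing in several records counts once). Each distinct gene
#' contributes one count to every category it is annotated with; genes
#' absent from the map are tallied as unannotated. A `log10(total
#' events)` display radius is included for pie-chart style exports.
#'
#' @param records Tibble of (filtered) duplication records.
#' @param gene_categories Tibble from [read_gene_categories()] (or any
#'   data frame with `gene_id`, `category_id` and optionally
#'   `namespace`).
#' @return List with `nodes` (tibble `node`, `total_events`,
#'   `distinct_genes`, `unannotated_genes`, `log10_radius`) and
#'   `categories` (tibble `node`, `namespace`, `category_id`,
#'   `gene_count`, `proportion` — proportion of the node's distinct
#'   annotated gene-category assignments).
#' @export
integrate_annotations <- function(records, gene_categories) {
  stopifnot(all(c("gene_id", "category_id") %in% names(gene_categories)))
  if (!"namespace" %in% names(gene_categories)) {
    gene_categories$namespace <- "default"
  }
  nodes <- sort(unique(records$node))
  node_rows <- list()
  cat_rows <- list()
  for (nd in nodes) {
    idx <- which(records$node == nd)
    genes <- sort(unique(c(unlist(records$genes_1[idx]),
                           unlist(records$genes_2[idx]))))
    ann <- gene_categories[gene_categories$gene_id %in% genes, ]
    ann <- unique(ann[, c("gene_id", "namespace", "category_id")])
    unannotated <- sum(!genes %in% ann$gene_id)
    total <- length(idx)
    node_rows[[nd]] <- tibble::tibble(
      node = nd, total_events = total, distinct_genes = length(genes),
      unannotated_genes = unannotated,
      log10_radius = log10(total)
    )
    if (nrow(ann)) {
      key <- paste(ann$namespace, ann$category_id, sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      cat_rows[[nd]] <- tibble::tibble(
        node = nd,
        namespace = vapply(parts, `[`, character(1), 1),
        category_id = vapply(parts, `[`, character(1), 2),
        gene_count = as.integer(tab),
        proportion = as.integer(tab) / sum(tab)
      )
    }
  }
  cats <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    tibble::tibble(node = character(0), namespace = character(0),
                   category_id = character(0), gene_count = integer(0),
                   proportion = numeric(0))
  cats <- cats[order(cats$node, cats$namespace, -cats$gene_count,
                     cats$category_id), ]
  list(nodes = do.call(rbind, node_rows), categories = cats)
}

#' Welch t comparison of duplication totals between two node groups
#'
#' Compares terminal-node duplication totals between two taxon groups
#' (e.g. two orders) with the two-tailed unequal-variance t test.
#'
#' @param totals Named numeric vector from [node_totals()].
#' @param groups Named character vector node -> group label; exactly two
#'   labels, each covering at least two nodes.
#' @return One-row tibble from [stat_tests()] (`welch_t` row).
#' @export
compare_node_groups <- function(totals, groups) {
  nodes <- intersect(names(totals), names(groups))
  if (length(unique(groups[nodes])) != 2) {
    stop("exactly two node groups required", call. = FALSE)
  }
  res <- stat_tests(unname(totals[nodes]), groups[nodes])
  res[res$test == "welch_t", ]
}

#' Write per-node duplication summaries as TSV
#'
#' @param summary List from [integrate_annotations()].
#' @param path Output path for the node table; the category table is
#'   written next to it with suffix `_categories.tsv`.
#' @return `path`, invisibly.
#' @export
write_node_summaries <- function(summary, path) {
  utils::write.table(summary$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat_path <- sub("\\.tsv$", "_categories.tsv", path)
  if (identical(cat_path, path)) cat_path <- paste0(path, "_categories.tsv")
  utils::write.table(summary$categories, cat_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export node category counts as an iTOL pie-chart annotation file
#'
#' Writes a `DATASET_PIECHART` text annotation: one line per node with
#' its category gene counts, radius proportional to `log10` of the total
#' event count. Optionally restricted to each node's `top_k` most
#' abundant categories.
#'
#' @param summary List from [integrate_annotations()].
#' @param path Output path.
#' @param top_k Optional per-node cap on categories (most abundant
#'   first); `Inf` keeps all.
#' @param dataset_label Label shown in iTOL.
#' @return `path`, invisibly.
#' @export
write_itol_pies <- function(summary, path, top_k = Inf,
                            dataset_label = "Duplicated gene annotations") {
  cats <- summary$categories
  if (is.finite(top_k)) {
    cats <- do.call(rbind, lapply(split(cats, cats$node), function(d) {
      utils::head(d[order(-d$gene_count), ], top_k)
    }))
  }
  fields <- sort(unique(cats$category_id))
  palette <- grDevices::hcl.colors(max(length(fields), 1), "Dark 3")
  header <- c(
    "DATASET_PIECHART",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", dataset_label),
    "COLOR\t#ff0000",
    paste0("FIELD_LABELS\t", paste(fields, collapse = "\t")),
    paste0("FIELD_COLORS\t",
           paste(palette[seq_along(fields)], collapse = "\t")),
    "DATA"
  )
  data_lines <- vapply(summary$nodes$node, function(nd) {
    counts <- stats::setNames(rep(0L, length(fields)), fields)
    sub <- cats[cats$node == nd, ]
    counts[sub$category_id] <- sub$gene_count
    radius <- summary$nodes$log10_radius[summary$nodes$node == nd]
    paste(c(nd, "0", sprintf("%.4f", max(radius, 0.1)), counts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, data_lines), path)
  invisible(path)
}
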