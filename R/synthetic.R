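# Synthetic study fixtures with controlled statistical structure: module
# catalogues, class-structured KO annotation tables with
# transcriptome-style dropout, duplication tables on a ladder species
# tree with node-specific category enrichment, and QC summary files.
# Every draw is fixed by the config seed.

#' Synthetic study configuration
#'
#' Generative parameters for a synthetic comparative study. The defaults
#' emulate the structure of a four-class algal genome panel: grouped
#' assemblies with class-structured KO presence/absence, a subset of
#' modules differentially knocked out in one class each, extra KO loss
#' in transcriptome-sourced assemblies, and duplication events enriched
#' for a node-specific functional category.
#'
#' @param seed Integer master seed; fixes every draw (sub-generators use
#'   small fixed offsets).
#' @param groups Data frame with columns `label`, `n` (assemblies) and
#'   `source` (`genome`, `1KP` or `MMETSP`).
#' @param n_modules Number of synthetic modules.
#' @param blocks_per_module Integer range `c(min, max)` of blocks.
#' @param p_or_alternative Probability a block gains an OR alternative.
#' @param p_complex Probability a block alternative is a multi-KO
#'   complex.
#' @param complex_size Integer range of complex subunit counts.
#' @param p_core_present Baseline probability an assembly carries each
#'   module KO.
#' @param differential Data frame `module` (index into the module list),
#'   `group` (affected label), `knockout` (per-KO removal probability in
#'   the affected group).
#' @param dropout_1kp,dropout_mmetsp Extra per-KO loss probability for
#'   the respective transcriptome sources.
#' @param duplication List: `n_tips`, `events_per_node` range,
#'   `n_categories`, `enrichment_odds` (odds of the node's enriched
#'   category against each background category; 1 = no association),
#'   `p_unannotated`.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    groups = data.frame(
      label = c("Florideophyceae", "Bangiophyceae", "Cyanidiophyceae",
                "Porphyridiophyceae"),
      n = 8L,
      source = "genome",
      stringsAsFactors = FALSE),
    n_modules = 200L,
    blocks_per_module = c(3L, 6L),
    p_or_alternative = 0.3,
    p_complex = 0.25,
    complex_size = c(2L, 3L),
    p_core_present = 0.95,
    differential = data.frame(
      module = 1:10,
      group = rep(c("Florideophyceae", "Bangiophyceae", "Cyanidiophyceae",
                    "Porphyridiophyceae"), length.out = 10),
      knockout = 0.9,
      stringsAsFactors = FALSE),
    dropout_1kp = 0.30,
    dropout_mmetsp = 0.15,
    duplication = list(n_tips = 8L, events_per_node = c(3L, 12L),
                       n_categories = 10L, enrichment_odds = 8,
                       p_unannotated = 0.1)) {
  stopifnot(length(seed) == 1, is.numeric(seed), !is.na(seed),
            abs(seed) < 2^31 - 100)
  seed <- as.integer(seed)
  stopifnot(all(c("label", "n", "source") %in% names(groups)),
            nrow(groups) >= 1, !anyDuplicated(groups$label),
            all(groups$n >= 1),
            all(groups$source %in% c("genome", "1KP", "MMETSP")))
  probs <- c(p_or_alternative, p_complex, p_core_present, dropout_1kp,
             dropout_mmetsp, duplication$p_unannotated)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(length(blocks_per_module) == 2,
            blocks_per_module[1] >= 1,
            blocks_per_module[2] >= blocks_per_module[1],
            length(complex_size) == 2, complex_size[1] >= 2,
            complex_size[2] >= complex_size[1])
  if (!is.null(differential) && nrow(differential)) {
    stopifnot(all(c("module", "group", "knockout") %in% names(differential)),
              all(differential$module >= 1),
              all(differential$module <= n_modules),
              all(differential$group %in% groups$label),
              all(differential$knockout >= 0 & differential$knockout <= 1))
  }
  stopifnot(duplication$n_tips >= 4,
            duplication$events_per_node[1] >= 1,
            duplication$enrichment_odds >= 1,
            duplication$n_categories >= 2)
  structure(list(
    seed = seed, groups = groups, n_modules = as.integer(n_modules),
    blocks_per_module = as.integer(blocks_per_module),
    p_or_alternative = p_or_alternative, p_complex = p_complex,
    complex_size = as.integer(complex_size),
    p_core_present = p_core_present, differential = differential,
    dropout_1kp = dropout_1kp, dropout_mmetsp = dropout_mmetsp,
    duplication = duplication
  ), class = "synthetic_config")
}

#' Deterministic assembly ids of a config
#'
#' @param config A `synthetic_config`.
#' @return Tibble `assembly_id`, `group`, `source`.
#' @export
synthetic_assemblies <- function(config) {
  rows <- lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    tibble::tibble(
      assembly_id = sprintf("%s_%02d", g$label, seq_len(g$n)),
      group = g$label, source = g$source)
  })
  do.call(rbind, rows)
}

# sample one integer uniformly from [lo, hi]; safe when lo == hi
sample_range <- function(lo, hi) {
  if (lo == hi) lo else sample(lo:hi, 1)
}

MODULE_CLASSES <- c("Amino acid metabolism", "Carbohydrate metabolism",
                    "Energy metabolism", "Lipid metabolism",
                    "Metabolism of cofactors and vitamins",
                    "Nucleotide metabolism")

#' Generate synthetic module definitions
#'
#' Draws `n_modules` modules with unique ids and unique KO ids. Each
#' block has one primary alternative (a single orthologue, or a `+`
#' complex with probability `p_complex`) and gains a second OR
#' alternative with probability `p_or_alternative`. Every definition is
#' produced by serialising through [parse_definition()], so the output
#' is parseable by construction.
#'
#' @param config A `synthetic_config`.
#' @return Named list of `module_definition` objects.
#' @export
generate_modules <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, {
    ko_counter <- 0L
    next_ko <- function() {
      ko_counter <<- ko_counter + 1L
      sprintf("K%05d", 10000L + ko_counter)
    }
    alt_string <- function() {
      if (stats::runif(1) < config$p_complex) {
        size <- sample_range(config$complex_size[1], config$complex_size[2])
        paste(replicate(size, next_ko()), collapse = "+")
      } else {
        next_ko()
      }
    }
    mods <- lapply(seq_len(config$n_modules), function(i) {
      nb <- sample_range(config$blocks_per_module[1],
                         config$blocks_per_module[2])
      blocks <- vapply(seq_len(nb), function(b) {
        alts <- alt_string()
        if (stats::runif(1) < config$p_or_alternative) {
          alts <- paste(alts, alt_string(), sep = ",")
        }
        # multi-alternative blocks with a complex need grouping at the
        # top level only when they contain an OR; plain "a,b" terms are
        # already one space-free token
        alts
      }, character(1))
      mclass <- sample(MODULE_CLASSES, 1)
      parse_definition(paste(blocks, collapse = " "),
                       module_id = sprintf("M9%04d", i),
                       name = sprintf("synthetic module %d", i),
                       module_class = mclass,
                       module_category = paste("Synthetic", mclass))
    })
    names(mods) <- vapply(mods, function(m) m$module_id, character(1))
    mods
  })
}

#' Generate class-structured synthetic KO annotations
#'
#' Each assembly receives each module KO independently with
#' `p_core_present`; differential knockouts then remove the KOs of
#' designated modules in the affected group with the configured
#' probability; finally source-specific dropout removes surviving KOs
#' from transcriptome-sourced assemblies. A thin gene-id wrapper (one
#' gene per retained KO) is generated so annotation-table readers are
#' exercised.
#'
#' @param modules Named list from [generate_modules()].
#' @param config A `synthetic_config`.
#' @return List with `annotations` (list of `annotation_set`), `groups`
#'   (named character vector assembly id -> group label) and `metadata`
#'   (tibble `assembly_id`, `group`, `source`).
#' @export
generate_annotations <- function(modules, config) {
  stopifnot(inherits(config, "synthetic_config"))
  meta <- synthetic_assemblies(config)
  module_kos <- lapply(modules, ko_universe)
  diff <- config$differential
  withr::with_seed(config$seed + 2L, {
    annotations <- lapply(seq_len(nrow(meta)), function(i) {
      asm <- meta$assembly_id[i]
      grp <- meta$group[i]
      src <- meta$source[i]
      kos <- character(0)
      for (mi in seq_along(module_kos)) {
        mk <- module_kos[[mi]]
        keep <- stats::runif(length(mk)) < config$p_core_present
        if (!is.null(diff) && nrow(diff)) {
          hit <- which(diff$module == mi & diff$group == grp)
          for (h in hit) {
            keep <- keep & (stats::runif(length(mk)) >= diff$knockout[h])
          }
        }
        kos <- c(kos, mk[keep])
      }
      dropout <- switch(src, "1KP" = config$dropout_1kp,
                        "MMETSP" = config$dropout_mmetsp, 0)
      if (dropout > 0 && length(kos)) {
        kos <- kos[stats::runif(length(kos)) >= dropout]
      }
      kos <- sort(unique(kos))
      gene_to_ko <- if (length(kos)) {
        data.frame(gene_id = sprintf("%s_g%05d", asm, seq_along(kos)),
                   ko = kos, stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = character(0), ko = character(0))
      }
      annotation_set(asm, gene_to_ko = gene_to_ko)
    })
    names(annotations) <- meta$assembly_id
    list(annotations = annotations,
         groups = stats::setNames(meta$group, meta$assembly_id),
         metadata = meta)
  })
}

ladder_newick <- function(tips, node_prefix = "N") {
  stopifnot(length(tips) >= 2)
  nwk <- sprintf("(%s,%s)%s1", tips[1], tips[2], node_prefix)
  if (length(tips) > 2) {
    for (i in 3:length(tips)) {
      nwk <- sprintf("(%s,%s)%s%d", nwk, tips[i], node_prefix, i - 1L)
    }
  }
  paste0(nwk, ";")
}

#' Generate a synthetic duplication dataset
#'
#' Builds a ladderised species tree with labelled internal nodes, draws
#' duplication events on every node (tips and internal) with supports
#' uniform on `[0, 1]` — so a 0.5 support filter retains half the events
#' in expectation — and assigns each node's duplicated genes a
#' functional category with the node's enriched category weighted
#' `enrichment_odds` to 1 against each background category
#' (`enrichment_odds = 1` gives no node-category association).
#'
#' @param config A `synthetic_config`.
#' @return List with `tree` (`phylo`), `newick` (string), `records`
#'   (tibble in [read_duplications()] layout), `gene_categories`
#'   (tibble), and `enriched` (named vector node -> planted category).
#' @export
generate_duplications <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dup <- config$duplication
  withr::with_seed(config$seed + 3L, {
    tips <- sprintf("T%02d", seq_len(dup$n_tips))
    newick <- ladder_newick(tips)
    tree <- ape::read.tree(text = newick)
    nodes <- c(tree$tip.label, tree$node.label)
    categories <- sprintf("CAT%02d", seq_len(dup$n_categories))
    enriched <- stats::setNames(
      categories[(seq_along(nodes) - 1L) %% dup$n_categories + 1L], nodes)

    og <- 0L
    rec_rows <- list()
    gene_rows <- list()
    for (nd in nodes) {
      n_events <- sample_range(dup$events_per_node[1],
                               dup$events_per_node[2])
      pool <- sprintf("%s_g%03d", nd, seq_len(30))
      node_genes <- character(0)
      for (e in seq_len(n_events)) {
        og <- og + 1L
        g1 <- sample(pool, sample(1:3, 1))
        g2 <- sample(setdiff(pool, g1), sample(1:3, 1))
        node_genes <- unique(c(node_genes, g1, g2))
        rec_rows[[og]] <- tibble::tibble(
          orthogroup = sprintf("OG%07d", og), node = nd,
          gene_tree_node = sprintf("n%d", og),
          support = round(stats::runif(1), 3),
          type = sample(c("Terminal", "Non-Terminal"), 1),
          genes_1 = list(sort(g1)), genes_2 = list(sort(g2)))
      }
      annotated <- node_genes[stats::runif(length(node_genes)) >=
                                dup$p_unannotated]
      if (length(annotated)) {
        w <- rep(1, dup$n_categories)
        w[match(enriched[nd], categories)] <- dup$enrichment_odds
        cat_draw <- sample(categories, length(annotated), replace = TRUE,
                           prob = w / sum(w))
        gene_rows[[nd]] <- tibble::tibble(
          gene_id = annotated, namespace = "InterPro",
          category_id = cat_draw,
          category_name = paste("synthetic superfamily", cat_draw))
      }
    }
    records <- do.call(rbind, rec_rows)
    gene_categories <- do.call(rbind, gene_rows)
    gene_categories <- gene_categories[order(gene_categories$gene_id), ]
    list(tree = tree, newick = newick, records = records,
         gene_categories = gene_categories, enriched = enriched)
  })
}

fmt_pct <- function(x) sprintf("%.1f", x)

#' Generate synthetic QC fixture files
#'
#' Draws BUSCO percentages (consistent: single + duplicated = complete,
#' complete + fragmented + missing = 100), RepeatMasker category
#' percentages and protein sequences for every configured assembly, and
#' renders them in the corresponding file formats so that parsing the
#' rendered text recovers the drawn values exactly.
#'
#' @param config A `synthetic_config`.
#' @return Named list per assembly with elements `busco` (`values`,
#'   `text`), `repeats` (`values`, `text`) and `proteins` (`count`,
#'   `mean_length_aa`, `text`).
#' @export
generate_qc_fixtures <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  meta <- synthetic_assemblies(config)
  withr::with_seed(config$seed + 4L, {
    out <- lapply(meta$assembly_id, function(asm) {
      complete <- round(stats::runif(1, 20, 95), 1)
      single <- round(complete * stats::runif(1, 0.8, 1), 1)
      duplicated <- round(complete - single, 1)
      missing <- round(stats::runif(1, 0, 100 - complete), 1)
      fragmented <- round(100 - complete - missing, 1)
      n_markers <- 255L
      busco_vals <- list(assembly_id = asm, complete_pct = complete,
                         single_pct = single, duplicated_pct = duplicated,
                         fragmented_pct = fragmented, missing_pct = missing,
                         n_markers = n_markers)
      busco_text <- c(
        "# BUSCO version is: 5.4.3",
        "# The lineage dataset is: eukaryota_odb10",
        "",
        "\t***** Results: *****",
        "",
        sprintf("\tC:%s%%[S:%s%%,D:%s%%],F:%s%%,M:%s%%,n:%d",
                fmt_pct(complete), fmt_pct(single), fmt_pct(duplicated),
                fmt_pct(fragmented), fmt_pct(missing), n_markers),
        sprintf("\t%d\tComplete BUSCOs (C)",
                round(complete / 100 * n_markers)))

      pcts <- round(stats::runif(5, 0, 12), 2)  # retro, dna, simple,
                                                # unclassified, low-compl
      total <- round(sum(pcts), 2)
      genome_len <- 1000000L
      masked <- round(genome_len * total / 100)
      repeat_vals <- list(assembly_id = asm, total_masked_pct = total,
                          retroelements = pcts[1], dna_transposons = pcts[2],
                          simple_repeats = pcts[3], unclassified = pcts[4],
                          other = pcts[5])
      repeat_text <- c(
        "==================================================",
        sprintf("file name: %s.fa", asm),
        sprintf("sequences:            12"),
        sprintf("total length: %10d bp", genome_len),
        sprintf("bases masked: %10d bp ( %.2f %%)", masked, total),
        "==================================================",
        "               number of      length   percentage",
        "               elements*    occupied  of sequence",
        "--------------------------------------------------",
        sprintf("Retroelements      %6d %10d bp %7.2f %%",
                50L, round(genome_len * pcts[1] / 100), pcts[1]),
        sprintf("DNA transposons    %6d %10d bp %7.2f %%",
                40L, round(genome_len * pcts[2] / 100), pcts[2]),
        "",
        "Total interspersed repeats:",
        "",
        sprintf("Simple repeats     %6d %10d bp %7.2f %%",
                30L, round(genome_len * pcts[3] / 100), pcts[3]),
        sprintf("Low complexity     %6d %10d bp %7.2f %%",
                20L, round(genome_len * pcts[5] / 100), pcts[5]),
        sprintf("Unclassified       %6d %10d bp %7.2f %%",
                10L, round(genome_len * pcts[4] / 100), pcts[4]),
        "--------------------------------------------------")

      count <- sample(20:40, 1)
      lens <- sample(50:400, count, replace = TRUE)
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      fasta <- unlist(lapply(seq_len(count), function(k) {
        seq <- paste(sample(aa, lens[k], replace = TRUE), collapse = "")
        if (stats::runif(1) < 0.5) seq <- paste0(seq, "*")
        c(sprintf(">%s_p%04d", asm, k), seq)
      }))
      list(busco = list(values = busco_vals, text = busco_text),
           repeats = list(values = repeat_vals, text = repeat_text),
           proteins = list(count = count, mean_length_aa = mean(lens),
                           text = fasta))
    })
    names(out) <- meta$assembly_id
    out
  })
}

#' Write duplication records in the OrthoFinder dialect
#'
#' @param records Tibble in the [read_duplications()] layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duplications <- function(records, path) {
  lines <- c(paste(DUP_COLUMNS, collapse = "\t"),
             vapply(seq_len(nrow(records)), function(i) {
               paste(records$orthogroup[i], records$node[i],
                     records$gene_tree_node[i],
                     format(records$support[i]), records$type[i],
                     paste(records$genes_1[[i]], collapse = ", "),
                     paste(records$genes_2[[i]], collapse = ", "),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene functional categories as TSV
#'
#' @param gene_categories Tibble from [generate_duplications()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_categories <- function(gene_categories, path) {
  utils::write.table(gene_categories, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Emit a complete synthetic fixture directory
#'
#' Writes every pipeline input the package consumes: `modules.tsv`,
#' per-assembly `annotations/*.tsv`, `metadata.tsv`,
#' `Duplications.tsv`, `tree.nwk`, `gene_annotations.tsv`,
#' `busco/*.txt`, `repeats/*.tbl`, `proteins/*.faa`, plus the config as
#' `config.yaml` for reproducibility.
#'
#' @param dir Output directory (created if needed).
#' @param config A `synthetic_config`.
#' @return `dir`, invisibly.
#' @export
simulate_study <- function(dir, config = synthetic_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("annotations", "busco", "repeats", "proteins")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  modules <- generate_modules(config)
  write_module_table(modules, file.path(dir, "modules.tsv"))
  ann <- generate_annotations(modules, config)
  for (a in ann$annotations) {
    utils::write.table(a$gene_to_ko,
                       file.path(dir, "annotations",
                                 paste0(a$assembly_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(ann$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dup <- generate_duplications(config)
  write_duplications(dup$records, file.path(dir, "Duplications.tsv"))
  writeLines(dup$newick, file.path(dir, "tree.nwk"))
  write_gene_categories(dup$gene_categories,
                        file.path(dir, "gene_annotations.tsv"))
  qc <- generate_qc_fixtures(config)
  for (asm in names(qc)) {
    writeLines(qc[[asm]]$busco$text,
               file.path(dir, "busco", paste0(asm, ".txt")))
    writeLines(qc[[asm]]$repeats$text,
               file.path(dir, "repeats", paste0(asm, ".tbl")))
    writeLines(qc[[asm]]$proteins$text,
               file.path(dir, "proteins", paste0(asm, ".faa")))
  }
  cfg <- unclass(config)
  cfg$groups <- as.list(as.data.frame(cfg$groups))
  if (!is.null(cfg$differential)) {
    cfg$differential <- as.list(as.data.frame(cfg$differential))
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
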