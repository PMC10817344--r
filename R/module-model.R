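# Boolean block model of KEGG-style metabolic pathway modules.
#
# A module DEFINITION string is an ordered sequence of blocks separated by
# top-level spaces; each block is one enzymatic step.  Within a block,
# `,` separates alternative orthologues (OR), `+` joins subunits of a
# complex (AND, binding tighter than `,`), a leading `-` marks an optional
# component, a bare `--` term denotes an undefined step and is skipped,
# and parentheses group recursively (spaces inside parentheses form nested
# AND groups without splitting top-level blocks).

#' Test KO identifier validity
#'
#' A KEGG Orthology identifier is `K` followed by exactly five digits.
#' Input is case-normalised to upper case before matching.
#'
#' @param x Character vector of candidate identifiers.
#' @return Logical vector.
#' @export
#' @examples
#' is_ko_id(c("K01853", "k00222", "K123", "KO1853"))
is_ko_id <- function(x) {
  grepl("^K[0-9]{5}$", toupper(trimws(x)))
}

normalise_ko <- function(x) toupper(trimws(x))

# ---- expression constructors -------------------------------------------

expr_atom <- function(ko, optional = FALSE) {
  ko <- normalise_ko(ko)
  if (!is_ko_id(ko)) {
    stop("malformed KO token '", ko, "'", call. = FALSE)
  }
  structure(list(kind = "atom", ko = ko, optional = optional),
            class = "ko_expr")
}

expr_and <- function(children) {
  stopifnot(length(children) >= 1)
  if (length(children) == 1) return(children[[1]])
  structure(list(kind = "and", children = children), class = "ko_expr")
}

expr_or <- function(children) {
  stopifnot(length(children) >= 1)
  if (length(children) == 1) return(children[[1]])
  structure(list(kind = "or", children = children), class = "ko_expr")
}

#' @export
print.ko_expr <- function(x, ...) {
  cat("<ko_expr> ", serialize_expr_block(x), "\n", sep = "")
  invisible(x)
}

# ---- low-level tokenising ----------------------------------------------

# Split `text` on single-character separators in `seps`, honouring
# parenthesis nesting; returns the pieces and the separator preceding each
# piece ("" for the first).
split_depth0 <- function(text, seps) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  pieces <- character(0)
  lead <- character(0)
  cur <- character(0)
  cur_lead <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced parentheses at position ", i, call. = FALSE)
      }
    }
    if (depth == 0L && ch %in% seps) {
      pieces <- c(pieces, paste(cur, collapse = ""))
      lead <- c(lead, cur_lead)
      cur <- character(0)
      cur_lead <- ch
    } else {
      cur <- c(cur, ch)
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses: ", depth, " unclosed '('", call. = FALSE)
  }
  pieces <- c(pieces, paste(cur, collapse = ""))
  lead <- c(lead, cur_lead)
  list(pieces = pieces, lead = lead)
}

check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("unbalanced parentheses at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses: ", depth, " unclosed '('", call. = FALSE)
  }
  invisible(TRUE)
}

# mark every atom beneath `expr` optional (used when `-` precedes a group)
mark_optional <- function(expr) {
  if (expr$kind == "atom") {
    expr$optional <- TRUE
    return(expr)
  }
  expr$children <- lapply(expr$children, mark_optional)
  expr
}

# ---- recursive-descent parsing -----------------------------------------

# sequence of space-separated terms; used for the whole definition and for
# the interior of parenthesised groups
parse_term_seq <- function(text, skip_dd = TRUE) {
  sp <- split_depth0(text, " ")
  terms <- sp$pieces[nzchar(sp$pieces)]
  terms <- terms[!(skip_dd & terms == "--")]
  lapply(terms, parse_or_level)
}

parse_or_level <- function(text) {
  sp <- split_depth0(text, ",")
  if (any(!nzchar(sp$pieces))) {
    stop("empty OR alternative in '", text, "'", call. = FALSE)
  }
  expr_or(lapply(sp$pieces, parse_chain))
}

# `+`/`-` chain of components; a component preceded by `-` is optional
parse_chain <- function(text) {
  if (!nzchar(text)) stop("empty block component", call. = FALSE)
  sp <- split_depth0(text, c("+", "-"))
  pieces <- sp$pieces
  lead <- sp$lead
  # a leading "-" produces an empty first piece: drop it, the next piece
  # inherits the "-" lead
  keep <- nzchar(pieces)
  if (!keep[1] && lead[2] %in% c("-", "+") && length(pieces) > 1) {
    # "-K00001..." or pathological "+K..."; only "-" is legal at the start
    if (lead[2] == "+") stop("block cannot start with '+'", call. = FALSE)
  }
  # "+-K00002" splits as lead '+' piece "" then lead '-' piece "K00002";
  # empty interior pieces are only legal when bridging "+-"
  comps <- list()
  optional <- logical(0)
  pending_opt <- FALSE
  for (i in seq_along(pieces)) {
    if (lead[i] == "-") pending_opt <- TRUE
    if (!nzchar(pieces[i])) {
      if (i == 1) next               # leading separator handled via lead[2]
      if (lead[i] == "+") next       # "+-" bridge
      stop("empty component in '", text, "'", call. = FALSE)
    }
    comps <- c(comps, list(parse_component(pieces[i], pending_opt)))
    optional <- c(optional, pending_opt)
    pending_opt <- FALSE
  }
  if (length(comps) == 0) stop("empty block component", call. = FALSE)
  expr_and(comps)
}

parse_component <- function(text, optional = FALSE) {
  if (startsWith(text, "(")) {
    if (!endsWith(text, ")")) {
      stop("malformed group '", text, "'", call. = FALSE)
    }
    inner <- substr(text, 2L, nchar(text) - 1L)
    sub <- parse_term_seq(inner)
    if (length(sub) == 0) {
      stop("empty parenthesised group in '", text, "'", call. = FALSE)
    }
    e <- expr_and(sub)
    if (optional) e <- mark_optional(e)
    return(e)
  }
  expr_atom(text, optional = optional)
}

#' Parse a module definition string
#'
#' Parses a KEGG-DEFINITION-style boolean expression into an ordered list
#' of blocks. Top-level space-separated terms become blocks (the module is
#' their conjunction); within a block `,` separates alternatives and `+`
#' joins complex subunits, binding tighter than `,`. A component preceded
#' by `-` is optional: it is excluded from satisfaction requirements, from
#' [ko_universe()] and from step counts (when `-` precedes a parenthesised
#' group the flag is propagated to every orthologue inside). A bare `--`
#' term (an undefined step) is skipped entirely and not counted as a
#' block. Parentheses group recursively; spaces inside parentheses form
#' nested AND groups without splitting top-level blocks.
#'
#' @param text Definition string, e.g. `"K01853 (K08246,K09717) K00222"`.
#' @param module_id Module identifier (`M` + five digits by KEGG
#'   convention; not enforced).
#' @param name Human-readable module name.
#' @param module_class Coarse class, e.g. `"Lipid metabolism"`.
#' @param module_category Finer category within the class.
#' @return A `module_definition`: list with fields `module_id`, `name`,
#'   `module_class`, `module_category` and `blocks` (list of expression
#'   trees in definition order).
#' @seealso [serialize_module()], [ko_universe()], [grade_module()]
#' @export
#' @examples
#' m <- parse_definition("K01853 (K08246,K09717) K00222", "M00917")
#' length(m$blocks)
parse_definition <- function(text, module_id = "", name = "",
                             module_class = "", module_category = "") {
  if (is.null(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop("empty module definition", call. = FALSE)
  }
  text <- trimws(text)
  check_balanced(text)
  blocks <- parse_term_seq(text)
  if (length(blocks) == 0) {
    stop("module '", module_id,
         "' has no blocks after skip rules", call. = FALSE)
  }
  structure(
    list(module_id = module_id, name = name, module_class = module_class,
         module_category = module_category, blocks = blocks),
    class = "module_definition"
  )
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id,
      if (nzchar(x$name)) paste0(" (", x$name, ")"), "\n",
      "  class: ", x$module_class,
      if (nzchar(x$module_category)) paste0(" / ", x$module_category), "\n",
      "  ", length(x$blocks), " block(s): ", serialize_module(x), "\n",
      sep = "")
  invisible(x)
}

# ---- serialisation ------------------------------------------------------

serialize_expr_block <- function(e) {
  switch(e$kind,
    atom = paste0(if (isTRUE(e$optional)) "-", e$ko),
    or   = paste(vapply(e$children, serialize_expr_alt, character(1)),
                 collapse = ","),
    and  = paste(vapply(e$children, serialize_expr_factor, character(1)),
                 collapse = "+")
  )
}

# inside an OR alternative: AND joins with "+", nested OR needs parentheses
serialize_expr_alt <- function(e) {
  switch(e$kind,
    atom = serialize_expr_block(e),
    and  = serialize_expr_block(e),
    or   = paste0("(", serialize_expr_block(e), ")")
  )
}

# inside an AND chain: nested AND renders as a space-joined parenthesised
# group so reparsing preserves structure; OR needs parentheses
serialize_expr_factor <- function(e) {
  switch(e$kind,
    atom = serialize_expr_block(e),
    or   = paste0("(", serialize_expr_block(e), ")"),
    and  = paste0("(",
                  paste(vapply(e$children, serialize_expr_block,
                               character(1)), collapse = " "),
                  ")")
  )
}

#' Serialise a module back to its definition string
#'
#' Canonical form: blocks joined by single spaces, no spaces inside
#' blocks, optional atoms prefixed `-`. Reparsing the output yields a
#' structurally identical module.
#'
#' @param module A `module_definition`.
#' @return Definition string.
#' @export
#' @examples
#' m <- parse_definition("K00100+K00101 K00102", "M00001")
#' serialize_module(m)
serialize_module <- function(module) {
  stopifnot(inherits(module, "module_definition"))
  paste(vapply(module$blocks, serialize_expr_block, character(1)),
        collapse = " ")
}

# ---- KO universe --------------------------------------------------------

collect_kos <- function(e, include_optional = FALSE) {
  if (e$kind == "atom") {
    if (isTRUE(e$optional) && !include_optional) return(character(0))
    return(e$ko)
  }
  unlist(lapply(e$children, collect_kos, include_optional = include_optional))
}

#' Required orthologue universe of a module
#'
#' All non-optional KO identifiers appearing anywhere in the module's
#' blocks. A module is graded absent exactly when an assembly carries none
#' of these.
#'
#' @param module A `module_definition`.
#' @param include_optional Include `-`-marked optional orthologues too.
#' @return Sorted character vector of KO ids.
#' @export
ko_universe <- function(module, include_optional = FALSE) {
  stopifnot(inherits(module, "module_definition"))
  sort(unique(unlist(
    lapply(module$blocks, collect_kos, include_optional = include_optional)
  )))
}

# ---- module file I/O ----------------------------------------------------

#' Read a tab-separated module table
#'
#' Plain-text module catalogue, one record per line:
#' `module_id<TAB>name<TAB>class<TAB>category<TAB>definition`.
#'
#' @param path File path.
#' @return List of `module_definition` objects, named by module id.
#' @export
read_module_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("module_id", "name", "class",
                                         "category", "definition"))
  mods <- lapply(seq_len(nrow(tab)), function(i) {
    parse_definition(tab$definition[i], module_id = tab$module_id[i],
                     name = tab$name[i], module_class = tab$class[i],
                     module_category = tab$category[i])
  })
  names(mods) <- tab$module_id
  mods
}

#' Write modules to a tab-separated module table
#'
#' @param modules List of `module_definition` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(m$module_id, m$name, m$module_class, m$module_category,
          serialize_module(m), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read KEGG flat-file style module records
#'
#' Parses records in the KEGG flat-file layout: fields start with a
#' keyword in column 1 (`ENTRY`, `NAME`, `DEFINITION`, `CLASS`),
#' continuation lines are indented, records end with `///`. The `CLASS`
#' field's semicolon-separated levels are mapped to module class (second
#' level) and category (third level) when present.
#'
#' @param path File path.
#' @return List of `module_definition` objects, named by module id.
#' @export
read_kegg_flatfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "///")))
  mods <- list()
  for (rec in recs) {
    rec <- rec[rec != "///"]
    if (!length(rec) || !any(grepl("^ENTRY", rec))) next
    fields <- list()
    key <- NULL
    for (ln in rec) {
      if (grepl("^[A-Z_]+", ln)) {
        key <- sub("^([A-Z_]+).*", "\\1", ln)
        val <- trimws(sub("^[A-Z_]+\\s*", "", ln))
        fields[[key]] <- val
      } else if (!is.null(key)) {
        fields[[key]] <- paste(fields[[key]], trimws(ln))
      }
    }
    entry <- strsplit(fields$ENTRY, "\\s+")[[1]][1]
    cls <- character(0)
    if (!is.null(fields$CLASS)) {
      cls <- trimws(strsplit(fields$CLASS, ";")[[1]])
    }
    mods[[entry]] <- parse_definition(
      fields$DEFINITION, module_id = entry,
      name = if (is.null(fields$NAME)) "" else fields$NAME,
      module_class = if (length(cls) >= 2) cls[2] else "",
      module_category = if (length(cls) >= 3) cls[3] else ""
    )
  }
  mods
}
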