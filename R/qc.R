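# Assembly quality control: BUSCO short-summary parsing, the study's
# completeness gate, RepeatMasker .tbl collation and protein statistics.

#' Parse a BUSCO short summary
#'
#' Extracts the score line
#' `C:x%[S:x%,D:x%],F:x%,M:x%,n:N` from a BUSCO `short_summary*.txt`.
#'
#' @param text Character vector of file lines, or a file path.
#' @param assembly_id Assembly id to attach.
#' @return List with `assembly_id`, `complete_pct`, `single_pct`,
#'   `duplicated_pct`, `fragmented_pct`, `missing_pct`, `n_markers`.
#' @export
parse_busco_summary <- function(text, assembly_id = "") {
  if (length(text) == 1 && file.exists(text)) {
    if (!nzchar(assembly_id)) {
      assembly_id <- sub("\\.[^.]*$", "", basename(text))
    }
    text <- readLines(text, warn = FALSE)
  }
  pat <- paste0("C:([0-9.]+)%\\[S:([0-9.]+)%,D:([0-9.]+)%\\],",
                "F:([0-9.]+)%,M:([0-9.]+)%,n:([0-9]+)")
  hit <- regmatches(text, regexec(pat, text))
  hit <- hit[lengths(hit) == 7]
  if (!length(hit)) {
    stop("no BUSCO score line (C:..%[S:..%,D:..%],F:..%,M:..%,n:..) found",
         call. = FALSE)
  }
  v <- as.numeric(hit[[1]][-1])
  list(assembly_id = assembly_id, complete_pct = v[1], single_pct = v[2],
       duplicated_pct = v[3], fragmented_pct = v[4], missing_pct = v[5],
       n_markers = as.integer(v[6]))
}

#' Assembly-quality gate on BUSCO completeness
#'
#' Pass requires complete at least `min_complete` percent AND missing
#' strictly below `max_missing` percent.
#'
#' @param score List from [parse_busco_summary()] (needs `complete_pct`
#'   and `missing_pct`).
#' @param min_complete Inclusive lower bound on complete percent.
#' @param max_missing Exclusive upper bound on missing percent.
#' @return Logical pass flag.
#' @export
#' @examples
#' qc_gate(list(complete_pct = 35, missing_pct = 49.9))  # TRUE
#' qc_gate(list(complete_pct = 90, missing_pct = 50))    # FALSE
qc_gate <- function(score, min_complete = 35.0, max_missing = 50.0) {
  score$complete_pct >= min_complete && score$missing_pct < max_missing
}

# percentage at the end of a RepeatMasker summary line like
# "Retroelements          100       100000 bp   10.00 %"
rm_line_pct <- function(lines, label) {
  hit <- grep(paste0("^\\s*", label), lines, value = TRUE)
  if (!length(hit)) return(0)
  m <- regmatches(hit[1], regexec("([0-9.]+)\\s*%", hit[1]))[[1]]
  if (length(m) < 2) return(0)
  as.numeric(m[2])
}

#' Parse a RepeatMasker .tbl summary
#'
#' Collates repeat percentages into the overarching categories
#' retroelements, DNA transposons, simple repeats and unclassified;
#' every other tabulated category (satellites, small RNA, low
#' complexity, rolling circles) is pooled into `other`. The total comes
#' from the `bases masked` line, which must be present.
#'
#' @param text Character vector of file lines, or a file path.
#' @param assembly_id Assembly id to attach.
#' @return List with `assembly_id`, `total_masked_pct`, `retroelements`,
#'   `dna_transposons`, `simple_repeats`, `unclassified`, `other`.
#' @export
parse_repeatmasker_tbl <- function(text, assembly_id = "") {
  if (length(text) == 1 && file.exists(text)) {
    if (!nzchar(assembly_id)) {
      assembly_id <- sub("\\.[^.]*$", "", basename(text))
    }
    text <- readLines(text, warn = FALSE)
  }
  masked_line <- grep("bases masked", text, value = TRUE)
  if (!length(masked_line)) {
    stop("no 'bases masked' line in RepeatMasker table", call. = FALSE)
  }
  m <- regmatches(masked_line[1],
                  regexec("\\(\\s*([0-9.]+)\\s*%\\s*\\)", masked_line[1]))[[1]]
  if (length(m) < 2) {
    stop("could not read masked percentage from: ", masked_line[1],
         call. = FALSE)
  }
  other <- sum(vapply(c("Rolling-circles", "Satellites", "Small RNA",
                        "Low complexity"),
                      function(lb) rm_line_pct(text, lb), numeric(1)))
  list(
    assembly_id = assembly_id,
    total_masked_pct = as.numeric(m[2]),
    retroelements = rm_line_pct(text, "Retroelements"),
    dna_transposons = rm_line_pct(text, "DNA transposons"),
    simple_repeats = rm_line_pct(text, "Simple repeats"),
    unclassified = rm_line_pct(text, "Unclassified"),
    other = other
  )
}

#' Protein count and mean length from a FASTA file
#'
#' Stop characters (`*`) are stripped before length counting; the mean
#' is taken over all sequences without any length filtering.
#'
#' @param path Protein FASTA path.
#' @param assembly_id Assembly id to attach.
#' @return List with `assembly_id`, `protein_count`, `mean_length_aa`
#'   (`NA` with `undefined = TRUE` for an empty file).
#' @export
protein_stats <- function(path,
                          assembly_id = sub("\\.[^.]*$", "",
                                            basename(path))) {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- length(seqs)
  if (n == 0) {
    return(list(assembly_id = assembly_id, protein_count = 0L,
                mean_length_aa = NA_real_, undefined = TRUE))
  }
  stops <- Biostrings::letterFrequency(seqs, "*")[, 1]
  lens <- Biostrings::width(seqs) - stops
  list(assembly_id = assembly_id, protein_count = n,
       mean_length_aa = mean(lens), undefined = FALSE)
}

#' Combined per-assembly QC table
#'
#' Joins parsed BUSCO scores, repeat summaries and protein statistics on
#' assembly id and applies [qc_gate()].
#'
#' @param busco_scores List of [parse_busco_summary()] results.
#' @param repeat_summaries Optional list of [parse_repeatmasker_tbl()]
#'   results.
#' @param protein_statistics Optional list of [protein_stats()] results.
#' @param min_complete,max_missing Gate thresholds.
#' @return Tibble, one row per assembly, with a logical `qc_pass`.
#' @export
qc_table <- function(busco_scores, repeat_summaries = NULL,
                     protein_statistics = NULL, min_complete = 35.0,
                     max_missing = 50.0) {
  rows <- lapply(busco_scores, function(b) {
    row <- tibble::as_tibble(b)
    row$qc_pass <- qc_gate(b, min_complete, max_missing)
    row
  })
  out <- do.call(rbind, rows)
  merge_on <- function(out, extra) {
    df <- do.call(rbind, lapply(extra, tibble::as_tibble))
    tibble::as_tibble(merge(out, df, by = "assembly_id", all.x = TRUE))
  }
  if (!is.null(repeat_summaries)) out <- merge_on(out, repeat_summaries)
  if (!is.null(protein_statistics)) {
    out <- merge_on(out, protein_statistics)
  }
  out[order(out$assembly_id), ]
}
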