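# Independent oracles and random-case generators for property tests.
# The oracle evaluates block expressions by compiling them to plain R
# boolean code and eval()ing it -- a code path disjoint from the
# package's recursive evaluator.

oracle_expr_code <- function(e) {
  switch(e$kind,
    atom = if (isTRUE(e$optional)) "TRUE" else
      sprintf('("%s" %%in%% kos)', e$ko),
    and = paste0("(", paste(vapply(e$children, oracle_expr_code,
                                   character(1)), collapse = " & "), ")"),
    or = paste0("(", paste(vapply(e$children, oracle_expr_code,
                                  character(1)), collapse = " | "), ")")
  )
}

oracle_satisfied <- function(expr, kos) {
  eval(parse(text = oracle_expr_code(expr)), list(kos = kos))
}

# block-count category re-derived from first principles
oracle_block_category <- function(n_present, n_total) {
  if (n_present == 0) return("ABSENT")
  miss <- n_total - n_present
  if (miss == 0) "COMPLETE" else if (miss == 1) "MISSING_1" else
    if (miss == 2) "MISSING_2" else "INCOMPLETE"
}

# small random module over a shared KO pool so annotation overlap is
# common; <= 6 blocks, <= 6 required orthologues per block
KO_POOL <- sprintf("K%05d", 1:12)

random_block_string <- function(p_optional = 0.1) {
  style <- sample(c("atom", "complex", "or"), 1,
                  prob = c(0.4, 0.3, 0.3))
  piece <- function(n) {
    kos <- sample(KO_POOL, n)
    opt <- stats::runif(n) < p_optional
    opt[1] <- FALSE  # keep at least one required orthologue
    paste0(ifelse(opt, "-", ""), kos, collapse = "+")
  }
  switch(style,
    atom = piece(1),
    complex = piece(sample(2:4, 1)),
    or = paste(piece(sample(1:3, 1)), piece(sample(1:3, 1)), sep = ","))
}

random_module <- function(id = "M99999", max_blocks = 6) {
  nb <- sample(1:max_blocks, 1)
  def <- paste(replicate(nb, random_block_string()), collapse = " ")
  parse_definition(def, module_id = id)
}

random_ko_set <- function() {
  n <- sample(0:length(KO_POOL), 1)
  if (n == 0) character(0) else sample(KO_POOL, n)
}

# shared small synthetic config for fast tests
small_config <- function(seed = 7) {
  synthetic_config(
    seed = seed, n_modules = 20,
    differential = data.frame(module = 1:2, group = "Cyanidiophyceae",
                              knockout = 0.9),
    groups = data.frame(
      label = c("Florideophyceae", "Bangiophyceae", "Cyanidiophyceae",
                "Porphyridiophyceae"),
      n = 4L, source = "genome", stringsAsFactors = FALSE))
}
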