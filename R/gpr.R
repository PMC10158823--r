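# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids
# with AND/OR and parentheses (keywords case-insensitive).  An empty rule
# means "unconditionally present".  Parsing is a small recursive-descent
# over the grammar
#   expr   := term (OR term)*
#   term   := factor (AND factor)*
#   factor := gene | "(" expr ")"

gpr_tokenize <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  # gene ids: anything that is not whitespace or a parenthesis
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  toks <- regmatches(rule, list(m))[[1]]
  toks
}

gpr_parse <- function(rule) {
  toks <- gpr_tokenize(rule)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw
  parse_expr <- function() {
    node <- parse_term()
    while (is_kw(peek(), "or")) {
      advance()
      node <- list(op = "or", left = node, right = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_kw(peek(), "and")) {
      advance()
      node <- list(op = "and", left = node, right = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene rule: unexpected end of '", rule, "'",
                       call. = FALSE)
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("malformed gene rule: missing ')' in '", rule, "'", call. = FALSE)
      }
      advance()
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("malformed gene rule: unexpected '", t, "' in '", rule, "'",
           call. = FALSE)
    }
    advance()
    list(op = "gene", id = t)
  }
  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("malformed gene rule: trailing '", toks[pos], "' in '", rule, "'",
         call. = FALSE)
  }
  tree
}

gpr_tree_genes <- function(node) {
  if (is.null(node)) return(character())
  if (node$op == "gene") return(node$id)
  c(gpr_tree_genes(node$left), gpr_tree_genes(node$right))
}

# All gene ids mentioned in a rule (empty rule -> character(0)).
gpr_genes <- function(rule) {
  unique(gpr_tree_genes(gpr_parse(rule)))
}

gpr_tree_eval <- function(node, deleted) {
  if (is.null(node)) return(TRUE)
  switch(node$op,
    gene = !(node$id %in% deleted),
    and = gpr_tree_eval(node$left, deleted) && gpr_tree_eval(node$right, deleted),
    or = gpr_tree_eval(node$left, deleted) || gpr_tree_eval(node$right, deleted)
  )
}

#' Evaluate a gene-protein-reaction rule under gene deletions
#'
#' Standard GPR semantics: deleted genes evaluate to `FALSE`, all other
#' genes to `TRUE`; `and`/`or` combine isozyme and complex requirements;
#' an empty rule means the reaction is unconditionally available.
#'
#' @param rule A GPR string, e.g. `"(g1 and g2) or g3"`.  Keywords are
#'   case-insensitive; gene ids may contain any non-space, non-parenthesis
#'   characters.
#' @param deleted Character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains catalysable, `FALSE` otherwise.
#' @examples
#' evaluate_gene_rule("aceF", "aceF")            # FALSE
#' evaluate_gene_rule("(g1 and g2) or g3", "g1") # TRUE
#' evaluate_gene_rule("", "anything")            # TRUE
#' @export
evaluate_gene_rule <- function(rule, deleted = character()) {
  gpr_tree_eval(gpr_parse(rule), deleted)
}
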