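# A small atom-selection language: conjunctions of equality tests on
# name / residue_name / residue_index / chain / group, e.g.
#   'residue_name == "ARG" and name == "CZ"'
#   'group == "ligand"'
# Values may be double-quoted or bare; `and`, `AND` and `&` are synonyms.

.tokenize_selection <- function(expr) {
  tokens <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    rest <- substr(expr, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws) && nzchar(ws)) { i <- i + nchar(ws); next }
    rest <- substr(expr, i, n)
    m <- regmatches(rest, regexpr('^("([^"]*)"|==|&&?|[A-Za-z_][A-Za-z0-9_]*|-?[0-9]+)', rest))
    if (!length(m) || !nzchar(m))
      stop(sprintf("selection parse error at position %d in '%s'", i, expr))
    tokens[[length(tokens) + 1L]] <- list(text = m[1], pos = i)
    i <- i + nchar(m[1])
  }
  tokens
}

#' Select atoms by expression
#'
#' Evaluates a conjunction of field tests against a topology and returns the
#' matching atom indices in ascending order.  Supported fields: `name`,
#' `residue_name`, `residue_index`, `chain` and `group` (named selections
#' stored in the topology).  An empty result is allowed but reported with a
#' `message()` so silent typos do not go unnoticed.
#'
#' @param top a [topology()] object.
#' @param expression selection string, e.g. `'name == "CA"'`.
#' @return Ascending integer vector of 1-based atom indices.
#' @export
select_atoms <- function(top, expression) {
  toks <- .tokenize_selection(expression)
  if (!length(toks))
    stop("selection parse error: empty expression")
  fields <- c("name", "residue_name", "residue_index", "chain", "group")
  keep <- rep(TRUE, n_atoms(top))
  k <- 1L
  expect_test <- TRUE
  while (k <= length(toks)) {
    if (!expect_test) {
      t <- toks[[k]]$text
      if (!(t %in% c("and", "AND", "&", "&&")))
        stop(sprintf("selection parse error at position %d: expected 'and', got '%s'",
                     toks[[k]]$pos, t))
      k <- k + 1L
      expect_test <- TRUE
      next
    }
    if (k + 2L > length(toks))
      stop(sprintf("selection parse error at position %d: incomplete test",
                   toks[[k]]$pos))
    field <- toks[[k]]$text
    op <- toks[[k + 1L]]$text
    val <- toks[[k + 2L]]$text
    if (!(field %in% fields))
      stop(sprintf("selection parse error at position %d: unknown field '%s'",
                   toks[[k]]$pos, field))
    if (op != "==")
      stop(sprintf("selection parse error at position %d: expected '==', got '%s'",
                   toks[[k + 1L]]$pos, op))
    val <- gsub('^"|"$', "", val)
    this <- if (field == "group") {
      if (is.null(top$groups[[val]]))
        stop(sprintf("selection error at position %d: unknown group '%s'",
                     toks[[k + 2L]]$pos, val))
      seq_len(n_atoms(top)) %in% top$groups[[val]]
    } else if (field == "residue_index") {
      iv <- suppressWarnings(as.integer(val))
      if (is.na(iv))
        stop(sprintf("selection parse error at position %d: residue_index needs an integer, got '%s'",
                     toks[[k + 2L]]$pos, val))
      top$atoms$residue_index == iv
    } else {
      top$atoms[[field]] == val
    }
    keep <- keep & this
    k <- k + 3L
    expect_test <- FALSE
  }
  if (expect_test)
    stop("selection parse error: expression ends after 'and'")
  out <- which(keep)
  if (!length(out))
    message("select_atoms: expression '", expression, "' matched no atoms")
  out
}
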