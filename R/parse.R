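# Text format: a small reagent-centric model language.
#
# Grammar (one statement per declaration, `//` comments to end of line):
#
#   parameter    :  name = number ;
#   kinetic law  :  kineticLawOf reaction : expression ;
#   species      :  name = term (+ term)* ;        term: (reaction [, coeff]) op
#                   op is one of  >>  <<  (+)  (-)
#   constants    :  constant name (, name)* ;
#   composition  :  name[count] <*> name[count] <*> ...   (last statement)
#
# Expressions are arithmetic (+ - * /, parentheses) over numbers, parameter
# names and species names.  Statement order is free except that the
# composition line comes last; every identifier must be declared somewhere
# in the file.

bp_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  toks <- list()
  pats <- c(
    WS = "^[ \t\r]+",
    COMMENT = "^//[^\n]*",
    NUMBER = "^(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?",
    IDENT = "^[A-Za-z_][A-Za-z0-9_]*",
    COMPOSE = "^<\\*>",
    LSHIFT = "^<<",
    RSHIFT = "^>>",
    PUNCT = "^[=;:(),+*/\\[\\]-]"
  )
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    col <- 1L
    while (nzchar(s)) {
      hit <- FALSE
      for (ty in names(pats)) {
        m <- regmatches(s, regexpr(pats[[ty]], s, perl = TRUE))
        if (length(m) && nzchar(m)) {
          if (!ty %in% c("WS", "COMMENT"))
            toks[[length(toks) + 1L]] <-
              list(type = if (ty == "PUNCT") m else ty,
                   value = m, line = ln, col = col)
          col <- col + nchar(m)
          s <- substr(s, nchar(m) + 1L, nchar(s))
          hit <- TRUE
          break
        }
      }
      if (!hit)
        stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                     ln, col, substr(s, 1, 1)), call. = FALSE)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "EOF", value = "",
                                    line = length(lines) + 1L, col = 1L)
  toks
}

# recursive-descent parser over the token stream; `st` is a mutable cursor
new_cursor <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks; env$i <- 1L
  env
}
peek <- function(cu, ahead = 0L) cu$toks[[min(cu$i + ahead, length(cu$toks))]]
advance <- function(cu) { t <- cu$toks[[cu$i]]; cu$i <- cu$i + 1L; t }
expect <- function(cu, type, what = type) {
  t <- peek(cu)
  if (t$type != type)
    stop(sprintf("syntax error at line %d, column %d: expected %s but found '%s'",
                 t$line, t$col, what, t$value), call. = FALSE)
  advance(cu)
}

parse_number <- function(cu) {
  neg <- FALSE
  if (peek(cu)$type == "-") { advance(cu); neg <- TRUE }
  t <- expect(cu, "NUMBER", "a number")
  v <- as.numeric(t$value)
  if (neg) -v else v
}

# expression grammar: expr := term (('+'|'-') term)*
#                     term := factor (('*'|'/') factor)*
#                     factor := NUMBER | IDENT | '(' expr ')' | '-' factor
parse_expr <- function(cu) {
  e <- parse_term(cu)
  while (peek(cu)$type %in% c("+", "-")) {
    op <- advance(cu)$type
    e <- call(op, e, parse_term(cu))
  }
  e
}
parse_term <- function(cu) {
  e <- parse_factor(cu)
  while (peek(cu)$type %in% c("*", "/")) {
    op <- advance(cu)$type
    e <- call(op, e, parse_factor(cu))
  }
  e
}
parse_factor <- function(cu) {
  t <- peek(cu)
  if (t$type == "NUMBER") return(as.numeric(advance(cu)$value))
  if (t$type == "IDENT") return(as.name(advance(cu)$value))
  if (t$type == "(") {
    advance(cu); e <- parse_expr(cu); expect(cu, ")"); return(e)
  }
  if (t$type == "-") { advance(cu); return(call("-", parse_factor(cu))) }
  stop(sprintf("syntax error at line %d, column %d: expected an expression but found '%s'",
               t$line, t$col, t$value), call. = FALSE)
}

# species term: '(' reaction [',' coeff] ')' role-op
parse_species_term <- function(cu) {
  expect(cu, "(")
  rx <- expect(cu, "IDENT", "a reaction name")$value
  coeff <- 1L
  if (peek(cu)$type == ",") {
    advance(cu)
    t <- expect(cu, "NUMBER", "a stoichiometric coefficient")
    coeff <- as.numeric(t$value)
    if (coeff < 1 || coeff != round(coeff))
      stop(sprintf("error at line %d, column %d: stoichiometric coefficient must be a positive integer",
                   t$line, t$col), call. = FALSE)
  }
  expect(cu, ")")
  t <- peek(cu)
  role <-
    if (t$type == "RSHIFT") { advance(cu); "product" }
    else if (t$type == "LSHIFT") { advance(cu); "reactant" }
    else if (t$type == "(") {
      advance(cu)
      sg <- peek(cu)
      r <- if (sg$type == "+") "activator"
           else if (sg$type == "-") "inhibitor"
           else stop(sprintf("syntax error at line %d, column %d: expected '+' or '-' inside a role operator",
                             sg$line, sg$col), call. = FALSE)
      advance(cu); expect(cu, ")")
      r
    }
    else stop(sprintf("syntax error at line %d, column %d: expected a role operator (>>, <<, (+), (-)) but found '%s'",
                      t$line, t$col, t$value), call. = FALSE)
  data.frame(reaction = rx, coeff = as.integer(coeff), role = role)
}

#' Parse a reagent-centric model from text
#'
#' Reads the package's model language (see the grammar in the package
#' vignette): parameter assignments, `kineticLawOf` definitions, species
#' behaviour declarations built from the role operators `>>` (product),
#' `<<` (reactant), `(+)` (activator) and `(-)` (inhibitor), an optional
#' `constant` annotation for environment-held species, and a final
#' composition line giving initial quantities as `A[1000] <*> B[0] ...`.
#' Pure mass-action laws are recognised structurally, which enables
#' [scale_model()] and the fast stochastic path.
#'
#' @param text Model source as a single string (or a character vector of
#'   lines, which is concatenated with newlines).
#' @return A validated `bp_model`.
#' @seealso [read_biopepa()] to parse a file, [format.bp_model()] /
#'   [write_biopepa()] for the inverse pretty-printer.
#' @examples
#' m <- parse_biopepa("
#'   c1 = 0.5;
#'   kineticLawOf decay : c1 * X;
#'   X = (decay, 1) <<;
#'   X[10]
#' ")
#' reaction_views(m)$decay
#' @export
parse_biopepa <- function(text) {
  text <- paste(text, collapse = "\n")
  cu <- new_cursor(bp_tokenize(text))

  parameters <- numeric()
  behaviours <- list()
  laws <- list()
  constant_species <- character()
  initial <- NULL

  repeat {
    t <- peek(cu)
    if (t$type == "EOF") break
    if (t$type == "IDENT" && t$value == "kineticLawOf") {
      advance(cu)
      rx <- expect(cu, "IDENT", "a reaction name")$value
      if (rx %in% names(laws))
        stop(sprintf("error at line %d: duplicate kinetic law for reaction '%s'",
                     t$line, rx), call. = FALSE)
      expect(cu, ":")
      e <- parse_expr(cu)
      expect(cu, ";")
      laws[[rx]] <- bp_law(rx, e)
    } else if (t$type == "IDENT" && t$value == "constant") {
      advance(cu)
      repeat {
        constant_species <- c(constant_species,
                              expect(cu, "IDENT", "a species name")$value)
        if (peek(cu)$type != ",") break
        advance(cu)
      }
      expect(cu, ";")
    } else if (t$type == "IDENT" && peek(cu, 1L)$type == "=") {
      name <- advance(cu)$value
      advance(cu)  # '='
      if (peek(cu)$type == "(") {
        if (name %in% names(behaviours))
          stop(sprintf("error at line %d: duplicate declaration of species '%s'",
                       t$line, name), call. = FALSE)
        terms <- list(parse_species_term(cu))
        while (peek(cu)$type == "+") {
          advance(cu)
          terms[[length(terms) + 1L]] <- parse_species_term(cu)
        }
        expect(cu, ";")
        behaviours[[name]] <- do.call(rbind, terms)
      } else {
        if (name %in% names(parameters))
          stop(sprintf("error at line %d: duplicate parameter '%s'",
                       t$line, name), call. = FALSE)
        parameters[name] <- parse_number(cu)
        expect(cu, ";")
      }
    } else if (t$type == "IDENT" && peek(cu, 1L)$type == "[") {
      # composition line: Name[count] <*> Name[count] ...
      initial <- numeric()
      repeat {
        nm <- expect(cu, "IDENT", "a species name")$value
        expect(cu, "[")
        cnt <- parse_number(cu)
        expect(cu, "]")
        if (nm %in% names(initial))
          stop(sprintf("error at line %d: species '%s' appears twice in the composition",
                       t$line, nm), call. = FALSE)
        initial[nm] <- cnt
        if (peek(cu)$type != "COMPOSE") break
        advance(cu)
      }
      if (peek(cu)$type == ";") advance(cu)
      t2 <- peek(cu)
      if (t2$type != "EOF")
        stop(sprintf("syntax error at line %d, column %d: the composition line must be the last statement",
                     t2$line, t2$col), call. = FALSE)
    } else {
      stop(sprintf("syntax error at line %d, column %d: unexpected '%s'",
                   t$line, t$col, t$value), call. = FALSE)
    }
  }

  if (is.null(initial))
    stop("model has no composition line (initial quantities)", call. = FALSE)
  miss <- setdiff(names(behaviours), names(initial))
  if (length(miss))
    stop("missing initial count for species '", miss[1L], "'", call. = FALSE)

  m <- bp_model(parameters = parameters, behaviours = behaviours,
                laws = laws, initial = initial,
                constant_species = constant_species)
  # structural mass-action recognition (fills mass_action_constant)
  for (r in reaction_names(m))
    m$laws[[r]]$mass_action_constant <- detect_mass_action(m, r)
  m
}

#' Read a model file
#'
#' @param path Path to a UTF-8 model file (conventionally `.biopepa`).
#' @return A validated `bp_model`.
#' @export
read_biopepa <- function(path) {
  parse_biopepa(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

deparse_expr <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = " ")

#' Pretty-print a model in its text format
#'
#' The canonical form: parameters, kinetic laws, species behaviours, the
#' `constant` annotation, then the composition line.  Parsing the output
#' reproduces a structurally identical model (round trip).
#'
#' @param x A `bp_model`.
#' @param ... Unused.
#' @return A character vector of source lines.
#' @export
format.bp_model <- function(x, ...) {
  out <- character()
  for (p in names(x$parameters))
    out <- c(out, sprintf("%s = %s;", p, deparse(x$parameters[[p]])))
  if (length(out)) out <- c(out, "")
  for (r in names(x$laws))
    out <- c(out, sprintf("kineticLawOf %s : %s;", r, deparse_expr(x$laws[[r]]$expr)))
  out <- c(out, "")
  for (s in names(x$behaviours)) {
    b <- x$behaviours[[s]]
    terms <- sprintf("(%s, %d) %s", b$reaction, b$coeff, bp_roles[b$role])
    out <- c(out, sprintf("%s = %s;", s, paste(terms, collapse = " + ")))
  }
  if (length(x$constant_species))
    out <- c(out, "", sprintf("constant %s;",
                              paste(x$constant_species, collapse = ", ")))
  comp <- sprintf("%s[%s]", names(x$initial),
                  vapply(as.numeric(x$initial), deparse, character(1)))
  c(out, "", paste(comp, collapse = " <*> "))
}

#' Write a model to a file in the text format
#'
#' @param model A `bp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biopepa <- function(model, path) {
  writeLines(format(model), path)
  invisible(path)
}
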