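#' Model-notation grammar for survival and resighting structures
#'
#' Constrained CJS models are written in a compact field notation:
#' `a(...)` declares age classes (the final class open-ended, e.g.
#' `a(1,2,>=3)`), `t` a time (year) effect, `col` a colony effect, and any
#' other identifier a named annual covariate. `.` denotes interaction, `+`
#' an additive effect, and `/` separates independent per-age-class blocks
#' (e.g. `a(1).t/a(>=2)`: time-dependent first year, constant afterwards).
#'
#' @param text a grammar string.
#' @return an object of class `cmr_formula`: the original `text`, a
#'   `segments` list (each with a `classes` data.frame and an `effects`
#'   list of `(op, name)` pairs), and a global `classes` table mapping
#'   age ranges to segments.
#' @examples
#' parse_model_spec("a(1).t/a(>=2)")
#' parse_model_spec("a(1,>=2)+t")
#' @export
parse_model_spec <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("model formula must be a non-empty string")
  src <- text
  txt <- gsub("≥", ">=", text)   # accept the typeset >= sign
  txt <- gsub("\\s+", "", txt)
  seg_strs <- split_top(txt, "/")
  segments <- lapply(seg_strs, parse_segment, src = src)
  # assemble the global, contiguous age-class table
  cls <- do.call(rbind, lapply(seq_along(segments), function(s) {
    cbind(segments[[s]]$classes, segment = s)
  }))
  cls <- cls[order(cls$from), , drop = FALSE]
  if (cls$from[1L] != 1L)
    stop("age classes must start at age 1 in '", src, "'")
  if (any(diff(cls$from) < 1L) || anyDuplicated(cls$from))
    stop("overlapping or duplicated age classes in '", src, "'")
  n <- nrow(cls)
  cls$to <- c(cls$from[-1L] - 1L, Inf)
  if (any(cls$open[-n]))
    stop("only the final age class may be open-ended in '", src, "'")
  cls$label <- ifelse(is.finite(cls$to),
                      ifelse(cls$from == cls$to, as.character(cls$from),
                             paste0(cls$from, "-", cls$to)),
                      paste0(">=", cls$from))
  rownames(cls) <- NULL
  structure(list(text = src, segments = segments, classes = cls),
            class = "cmr_formula")
}

# split on a single-character operator outside parentheses
split_top <- function(txt, op) {
  ch <- strsplit(txt, "")[[1]]
  depth <- 0L; cuts <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    else if (ch[i] == ")") depth <- depth - 1L
    else if (ch[i] == op && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(ch))
  out <- substring(txt, starts, ends)   # empty when start > end
  if (any(!nzchar(out))) stop("empty term around '", op, "' in formula")
  out
}

parse_segment <- function(seg, src) {
  pos <- 1L; n <- nchar(seg)
  classes <- NULL
  effects <- list()
  expect_term <- TRUE; first <- TRUE
  while (pos <= n) {
    rest <- substr(seg, pos, n)
    if (expect_term) {
      if (grepl("^a\\(", rest)) {
        close <- regexpr("\\)", rest)
        if (close < 0)
          stop(sprintf("syntax error at position %d of '%s': unclosed a(",
                       pos, src))
        inner <- substr(rest, 3L, close - 1L)
        if (!is.null(classes))
          stop("a() may appear once per '/'-segment in '", src, "'")
        if (!first)
          stop("a() must lead its segment in '", src, "'")
        classes <- parse_age_classes(inner, src)
        pos <- pos + close
      } else {
        m <- regexpr("^[A-Za-z][A-Za-z0-9_]*", rest)
        if (m < 0)
          stop(sprintf("syntax error at position %d of '%s'", pos, src))
        name <- regmatches(rest, m)
        op <- if (first) NA_character_ else attr(effects, "pending_op")
        effects[[length(effects) + 1L]] <- list(op = op, name = name)
        pos <- pos + attr(m, "match.length")
      }
      expect_term <- FALSE; first <- FALSE
    } else {
      op <- substr(seg, pos, pos)
      if (!op %in% c(".", "+"))
        stop(sprintf("syntax error at position %d of '%s': expected . or +",
                     pos, src))
      attr(effects, "pending_op") <- op
      pos <- pos + 1L
      expect_term <- TRUE
    }
  }
  if (expect_term)
    stop("formula segment ends with an operator in '", src, "'")
  if (is.null(classes))  # no a(): one open class over all ages
    classes <- data.frame(from = 1L, open = TRUE)
  # effects recorded with the operator that bound them
  effects <- lapply(seq_along(effects), function(i) {
    e <- effects[[i]]
    if (i > 1L && is.na(e$op))
      stop("internal grammar error in '", src, "'")
    e
  })
  list(classes = classes, effects = effects)
}

parse_age_classes <- function(inner, src) {
  if (!nzchar(inner)) stop("empty a() in '", src, "'")
  toks <- strsplit(inner, ",", fixed = TRUE)[[1]]
  open <- grepl("^>=", toks)
  ages <- suppressWarnings(as.integer(sub("^>=", "", toks)))
  if (anyNA(ages) || any(ages < 1L))
    stop("age classes must be positive integers in '", src, "'")
  if (any(open[-length(open)]))
    stop("only the last class in a() may be open (>=) in '", src, "'")
  if (is.unsorted(ages, strictly = TRUE))
    stop("age classes must be increasing in '", src, "'")
  data.frame(from = ages, open = c(rep(FALSE, length(ages) - 1L),
                                   open[length(open)]))
}

#' @export
print.cmr_formula <- function(x, ...) {
  cat("model formula:", x$text, "\n")
  for (s in seq_along(x$segments)) {
    seg <- x$segments[[s]]
    cls <- x$classes[x$classes$segment == s, , drop = FALSE]
    eff <- if (length(seg$effects))
      paste(vapply(seg$effects, function(e)
        paste0(ifelse(is.na(e$op), "", e$op), e$name), ""), collapse = " ")
    else "(constant)"
    cat(sprintf("  segment %d: ages %s -> %s\n", s,
                paste(cls$label, collapse = ","), eff))
  }
  invisible(x)
}

#' Pair survival and resighting formulas
#'
#' @param survival,resight grammar strings (see [parse_model_spec]).
#' @return a `cjs_model_spec` object with parsed `phi` and `p` formulas.
#' @export
cjs_model_spec <- function(survival, resight) {
  structure(list(phi = parse_model_spec(survival),
                 p = parse_model_spec(resight),
                 survival = survival, resight = resight),
            class = "cjs_model_spec")
}

#' @export
print.cjs_model_spec <- function(x, ...) {
  cat("CJS model: phi ~", x$survival, "| p ~", x$resight, "\n")
  invisible(x)
}

# age -> global class row index
classify_age <- function(age, classes) {
  findInterval(age, classes$from)
}

# names of covariates referenced by a parsed formula
formula_covariates <- function(pf) {
  nm <- unlist(lapply(pf$segments, function(s)
    vapply(s$effects, `[[`, "", "name")))
  setdiff(unique(nm), c("t", "col"))
}
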