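#' Capture-resight histories
#'
#' A `capture_histories` object holds one 0/1 detection vector per marked
#' individual over a shared axis of annual occasions, together with a colony
#' (group) label per individual. All individuals are assumed marked as
#' fledglings, so age at occasion `j` for an individual first detected at
#' occasion `c` is `j - c`.
#'
#' @param detections integer matrix (individuals x occasions) of 0/1 flags;
#'   every row must contain at least one 1.
#' @param occasions integer vector of calendar years, one per column,
#'   strictly increasing.
#' @param group character vector of colony labels (length 1 or nrow).
#' @param id optional individual labels; generated if `NULL`.
#' @return an object of class `capture_histories` with elements
#'   `detections`, `occasions`, `group`, `id`.
#' @export
capture_histories <- function(detections, occasions, group = "colony1",
                              id = NULL) {
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  if (!all(detections %in% c(0L, 1L)))
    stop("detections must contain only 0/1")
  occasions <- as.integer(occasions)
  if (length(occasions) != ncol(detections))
    stop("length(occasions) must equal ncol(detections)")
  if (is.unsorted(occasions, strictly = TRUE))
    stop("occasions must be strictly increasing years")
  if (any(rowSums(detections) == 0L))
    stop("every individual must have at least one detection")
  n <- nrow(detections)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) stop("group must have length 1 or nrow(detections)")
  if (is.null(id)) id <- paste0("ind", seq_len(n))
  if (anyDuplicated(id)) stop("individual ids must be unique")
  dimnames(detections) <- list(id, occasions)
  structure(list(detections = detections, occasions = occasions,
                 group = as.character(group), id = as.character(id)),
            class = "capture_histories")
}

#' @export
print.capture_histories <- function(x, ...) {
  cat("Capture-resight histories\n")
  cat(sprintf("  individuals : %d\n", nrow(x$detections)))
  cat(sprintf("  occasions   : %d (%d-%d)\n", length(x$occasions),
              min(x$occasions), max(x$occasions)))
  cat(sprintf("  groups      : %s\n",
              paste(unique(x$group), collapse = ", ")))
  cat(sprintf("  observations: %d\n", sum(x$detections)))
  invisible(x)
}

# occasion index of first detection, per individual
first_detection <- function(set) {
  max.col(set$detections == 1L, ties.method = "first")
}

#' Read encounter histories
#'
#' Two plain-text dialects are supported. `"inp"` is the classic MARK input:
#' one record per line, a 0/1 detection string, whitespace, one count per
#' group, and a terminating `;`. `"tabular"` is a CSV with columns
#' `id,group,<year1>,...,<yearT>` (header row carries the occasion years).
#'
#' @param path file path.
#' @param dialect `"inp"` or `"tabular"`.
#' @param occasions calendar years of the occasions; required for `"inp"`
#'   (the tabular header carries them).
#' @param groups group labels for the count columns of an `.inp` file.
#' @return a [capture_histories] object.
#' @export
read_histories <- function(path, dialect = c("inp", "tabular"),
                           occasions = NULL, groups = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "inp") {
    if (is.null(occasions))
      stop("occasions (calendar years) are required for the inp dialect")
    lines <- readLines(path, warn = FALSE)
    lines <- sub("/\\*.*\\*/", "", lines)         # inline comments
    keep <- grepl("\\S", lines)
    recs <- which(keep)
    det <- list(); grp <- list()
    for (ln in recs) {
      txt <- trimws(lines[ln])
      if (!grepl(";\\s*$", txt))
        stop(sprintf("line %d: missing terminating ';'", ln))
      txt <- sub(";\\s*$", "", txt)
      parts <- strsplit(txt, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("line %d: expected detection string and group counts", ln))
      hstr <- parts[1L]
      if (grepl("[^01]", hstr))
        stop(sprintf("line %d: illegal symbol in detection string '%s'",
                     ln, hstr))
      if (nchar(hstr) != length(occasions))
        stop(sprintf("line %d: detection string length %d != %d occasions",
                     ln, nchar(hstr), length(occasions)))
      counts <- suppressWarnings(as.integer(parts[-1L]))
      if (anyNA(counts) || any(counts < 0L))
        stop(sprintf("line %d: group counts must be non-negative integers", ln))
      v <- as.integer(strsplit(hstr, "")[[1]])
      if (sum(v) == 0L)
        stop(sprintf("line %d: history has no detections", ln))
      glab <- if (is.null(groups)) paste0("g", seq_along(counts)) else groups
      if (length(glab) != length(counts))
        stop(sprintf("line %d: %d group counts but %d group labels",
                     ln, length(counts), length(glab)))
      for (g in seq_along(counts)) {
        if (counts[g] > 0L) {
          det[[length(det) + 1L]] <-
            matrix(v, nrow = counts[g], ncol = length(v), byrow = TRUE)
          grp[[length(grp) + 1L]] <- rep(glab[g], counts[g])
        }
      }
    }
    if (!length(det)) stop("no records in ", path)
    capture_histories(do.call(rbind, det), occasions,
                      group = unlist(grp))
  } else {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]),
                                     c("id", "group")))
      stop("tabular dialect needs columns id,group,<years...>")
    yrs <- suppressWarnings(as.integer(names(tab)[-(1:2)]))
    if (anyNA(yrs)) stop("tabular header year columns must be integers")
    det <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (!all(det %in% c(0, 1)))
      stop("tabular detection flags must be 0/1")
    capture_histories(det, yrs, group = tab$group, id = tab$id)
  }
}

#' Write encounter histories
#'
#' @param set a [capture_histories] object.
#' @param path output file.
#' @param dialect `"inp"` or `"tabular"` (see [read_histories]).
#' @return `path`, invisibly.
#' @export
write_histories <- function(set, path, dialect = c("inp", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "inp") {
    glev <- unique(set$group)
    strs <- apply(set$detections, 1L, paste, collapse = "")
    counts <- vapply(glev, function(g) as.integer(set$group == g),
                     integer(nrow(set$detections)))
    lines <- paste0(strs, " ", apply(counts, 1L, paste, collapse = " "), ";")
    writeLines(lines, path)
  } else {
    tab <- data.frame(id = set$id, group = set$group,
                      set$detections, check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Merge disjoint history sets
#'
#' @param ... [capture_histories] objects sharing the same occasion axis.
#' @return a combined [capture_histories] object.
#' @export
merge_histories <- function(...) {
  sets <- list(...)
  occ <- sets[[1]]$occasions
  for (s in sets[-1])
    if (!identical(s$occasions, occ))
      stop("all sets must share the same occasion axis")
  ids <- unlist(lapply(sets, `[[`, "id"))
  if (anyDuplicated(ids))
    ids <- unlist(lapply(seq_along(sets), function(i)
      paste0("s", i, ".", sets[[i]]$id)))
  capture_histories(do.call(rbind, lapply(sets, `[[`, "detections")),
                    occ, group = unlist(lapply(sets, `[[`, "group")),
                    id = ids)
}

#' Summarize a history set
#'
#' @param object a [capture_histories] object.
#' @param ... unused.
#' @return list with `n_individuals`, `n_observations` (total detections,
#'   initial captures included), and `releases` (cohort x group table of
#'   first markings).
#' @export
summary.capture_histories <- function(object, ...) {
  fd <- first_detection(object)
  rel <- table(cohort = object$occasions[fd], group = object$group)
  out <- list(n_individuals = nrow(object$detections),
              n_observations = sum(object$detections),
              releases = rel)
  class(out) <- "summary.capture_histories"
  out
}

#' @export
print.summary.capture_histories <- function(x, ...) {
  cat(sprintf("%d individuals, %d observations\n",
              x$n_individuals, x$n_observations))
  cat("first markings by cohort x group:\n")
  print(x$releases)
  invisible(x)
}

#' Reduce histories to cohort m-arrays
#'
#' Builds the sufficient statistic of the CJS likelihood: for every stratum
#' (group, marking cohort, release occasion `i`) the number released `R`
#' (first markings plus re-releases of birds detected at `i`), the counts
#' `m[i, j]` of first re-encounters at each later occasion `j`, and the
#' number never seen again. Releases at the final occasion generate no
#' multinomial cells and are kept only in the totals.
#'
#' @param set a [capture_histories] object.
#' @return an object of class `marray`: `meta` (data.frame with `group`,
#'   `cohort`, `occasion`, `R`, `never`), matrix `m` (strata x occasions),
#'   plus `occasions`, `groups`, `n_individuals`, `n_observations`.
#' @export
build_marray <- function(set) {
  T <- length(set$occasions)
  det <- set$detections
  fd <- first_detection(set)
  key <- character(0)
  env <- new.env(parent = emptyenv())
  bump <- function(g, c, i, slot, j = NULL) {
    k <- paste(g, c, i, sep = "\r")
    rec <- env[[k]]
    if (is.null(rec))
      rec <- list(g = g, c = c, i = i, R = 0L, never = 0L,
                  m = integer(T))
    if (slot == "R") rec$R <- rec$R + 1L
    if (slot == "never") rec$never <- rec$never + 1L
    if (slot == "m") rec$m[j] <- rec$m[j] + 1L
    env[[k]] <- rec
    invisible(NULL)
  }
  for (ind in seq_len(nrow(det))) {
    occ <- which(det[ind, ] == 1L)
    g <- set$group[ind]; c0 <- fd[ind]
    for (l in seq_along(occ)) {
      i <- occ[l]
      bump(g, c0, i, "R")
      if (l < length(occ)) bump(g, c0, i, "m", occ[l + 1L])
      else if (i < T) bump(g, c0, i, "never")
      # a bird whose last detection is the final occasion contributes no cell
    }
  }
  recs <- as.list(env)
  ord <- order(vapply(recs, `[[`, "", "g"),
               vapply(recs, `[[`, 0L, "c"),
               vapply(recs, `[[`, 0L, "i"))
  recs <- recs[ord]
  meta <- data.frame(group = vapply(recs, `[[`, "", "g"),
                     cohort = vapply(recs, `[[`, 0L, "c"),
                     occasion = vapply(recs, `[[`, 0L, "i"),
                     R = vapply(recs, `[[`, 0L, "R"),
                     never = vapply(recs, `[[`, 0L, "never"),
                     stringsAsFactors = FALSE)
  m <- do.call(rbind, lapply(recs, `[[`, "m"))
  dimnames(m) <- list(NULL, set$occasions)
  rownames(meta) <- NULL
  structure(list(meta = meta, m = m, occasions = set$occasions,
                 groups = unique(set$group),
                 n_individuals = nrow(det),
                 n_observations = sum(det)),
            class = "marray")
}

#' @export
print.marray <- function(x, ...) {
  cat(sprintf("m-array: %d release strata, %d occasions, groups: %s\n",
              nrow(x$meta), length(x$occasions),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("released %d times (%d individuals, %d observations)\n",
              sum(x$meta$R), x$n_individuals, x$n_observations))
  invisible(x)
}

# conservation check: R_i = sum_j m_ij + never_i for every stratum
validate_marray <- function(ma) {
  ok <- ma$meta$R == rowSums(ma$m) + ma$meta$never
  # strata released at the final occasion have no cells: R counted, never 0
  final <- ma$meta$occasion == length(ma$occasions)
  ok[final] <- rowSums(ma$m[final, , drop = FALSE]) == 0L
  all(ok)
}
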