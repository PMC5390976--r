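# ModeSet: a deduplicated, normalized collection of exact flux vectors with a
# class tag each (efm, efv_bounded, efv_unbounded, efv_lineality, zero), tied
# to the defining network and (optionally) constraint set.
#
# Normalization policy: ray-like modes (efm, efv_unbounded, efv_lineality) are
# stored as primitive integer representatives (gcd of |entries| = 1, direction
# preserved); bounded EFVs and the zero EFV are unique points and are stored
# unscaled as reduced rationals.

MODE_CLASSES <- c("efm", "efv_bounded", "efv_unbounded", "efv_lineality", "zero")
RAY_CLASSES <- c("efm", "efv_unbounded", "efv_lineality")

#' Construct a mode set
#'
#' @param num,den k x n exact coefficient matrices (one row per mode).
#' @param classes character vector of mode classes, one of
#'   "efm", "efv_bounded", "efv_unbounded", "efv_lineality", "zero".
#' @param network the defining `metabolic_network`.
#' @param constraints the defining `constraint_set` (NULL for the flux cone).
#' @param reversible optional logical vector flagging reversible modes (modes
#'   whose support avoids every irreversible index, valid in both directions).
#' @param normalize re-normalize, deduplicate and sort (default TRUE).
#' @return an object of class `mode_set`.
#' @export
mode_set <- function(num, den = NULL, classes, network, constraints = NULL,
                     reversible = NULL, normalize = TRUE) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  k <- nrow(num)
  if (ncol(num) != n_reactions(network))
    stop("mode length does not match reaction count", call. = FALSE)
  if (length(classes) == 1) classes <- rep(classes, k)
  if (!all(classes %in% MODE_CLASSES))
    stop("unknown mode class", call. = FALSE)
  if (is.null(reversible)) reversible <- rep(FALSE, k)
  ms <- structure(list(num = num, den = den, classes = classes,
                       reversible = reversible, network = network,
                       constraints = constraints),
                  class = "mode_set")
  if (normalize) ms <- .normalize_mode_set(ms) else {
    colnames(ms$num) <- colnames(ms$den) <- network$reaction_ids
  }
  ms
}

.normalize_mode_set <- function(ms) {
  k <- nrow(ms$num)
  n <- ncol(ms$num)
  for (i in seq_len(k)) {
    if (ms$classes[i] %in% RAY_CLASSES) {
      if (all(ms$num[i, ] == 0)) stop("zero vector tagged as a ray class",
                                      call. = FALSE)
      v <- rat_primitive(ms$num[i, ], ms$den[i, ])
      # reversible/lineality representatives: first nonzero entry positive
      if (ms$reversible[i] || ms$classes[i] == "efv_lineality") {
        fz <- which(v != 0)[1]
        if (v[fz] < 0) v <- -v
      }
      ms$num[i, ] <- v
      ms$den[i, ] <- 1
    } else {
      r <- rat_norm(ms$num[i, ], ms$den[i, ])
      ms$num[i, ] <- r$num
      ms$den[i, ] <- r$den
    }
  }
  keys <- mode_keys(ms)
  keep <- !duplicated(keys)
  ms$num <- ms$num[keep, , drop = FALSE]
  ms$den <- ms$den[keep, , drop = FALSE]
  ms$classes <- ms$classes[keep]
  ms$reversible <- ms$reversible[keep]
  # deterministic order: lexicographic by support pattern, then entries
  k <- nrow(ms$num)
  if (k > 1) {
    supp <- (ms$num != 0) * 1
    approx <- ms$num / ms$den
    ord <- do.call(order, c(split(supp, col(supp)), split(approx, col(approx))))
    ms$num <- ms$num[ord, , drop = FALSE]
    ms$den <- ms$den[ord, , drop = FALSE]
    ms$classes <- ms$classes[ord]
    ms$reversible <- ms$reversible[ord]
  }
  colnames(ms$num) <- colnames(ms$den) <- ms$network$reaction_ids
  ms
}

# exact dedup keys: normalized value string + class
mode_keys <- function(ms, with_class = TRUE) {
  k <- nrow(ms$num)
  vals <- vapply(seq_len(k), function(i)
    paste(format_rational(ms$num[i, ], ms$den[i, ]), collapse = ","),
    character(1))
  if (with_class) paste(ms$classes, vals, sep = "|") else vals
}

#' Number of modes in a mode set
#' @param modes a `mode_set`.
#' @return integer count.
#' @export
n_modes <- function(modes) nrow(modes$num)

#' Supports of the modes
#' @param modes a `mode_set`.
#' @return list of integer index vectors, one per mode.
#' @export
mode_support <- function(modes)
  lapply(seq_len(n_modes(modes)), function(i) which(modes$num[i, ] != 0))

# subset while keeping metadata
mode_subset <- function(modes, idx) {
  modes$num <- modes$num[idx, , drop = FALSE]
  modes$den <- modes$den[idx, , drop = FALSE]
  modes$classes <- modes$classes[idx]
  modes$reversible <- modes$reversible[idx]
  modes
}

#' Modes as a character matrix of exact rationals
#' @param modes a `mode_set`.
#' @return k x n character matrix ("p/q" entries) with reaction id columns.
#' @export
mode_matrix <- function(modes) {
  k <- n_modes(modes)
  out <- matrix("0", k, ncol(modes$num), dimnames = dimnames(modes$num))
  for (i in seq_len(k))
    out[i, ] <- format_rational(modes$num[i, ], modes$den[i, ])
  out
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set with", n_modes(x), "modes (",
      paste(sprintf("%s: %d", names(table(x$classes)), table(x$classes)),
            collapse = ", "), ")\n")
  if (n_modes(x) > 0 && ncol(x$num) <= 12) {
    print(mode_matrix(x), quote = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.mode_set <- function(x, ...) {
  df <- as.data.frame(mode_matrix(x), stringsAsFactors = FALSE)
  df$mode_class <- x$classes
  df
}

#' Write a mode set to file
#'
#' TSV: one row per mode, reaction-id columns in network order with exact
#' "p/q" rationals (integers without "/1") plus a final `mode_class` column.
#' JSON: full metadata including the constraint rows the set was computed
#' under. Both round-trip losslessly through [read_modes()].
#'
#' @param modes a `mode_set`.
#' @param path output file.
#' @param format "tsv" or "json".
#' @export
write_modes <- function(modes, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(modes), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    k <- n_modes(modes)
    cons <- modes$constraints
    obj <- list(
      reaction_ids = modes$network$reaction_ids,
      modes = lapply(seq_len(k), function(i) list(
        coeffs = as.list(format_rational(modes$num[i, ], modes$den[i, ])),
        mode_class = modes$classes[i],
        reversible = modes$reversible[i])),
      constraints = if (is.null(cons) || !length(cons$h_num)) NULL else list(
        rows = lapply(seq_along(cons$h_num), function(i) list(
          coeffs = as.list(format_rational(cons$G_num[i, ], cons$G_den[i, ])),
          rhs = format_rational(cons$h_num[i], cons$h_den[i]),
          tag = cons$tags[i]))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(NULL)
}

#' Read a mode set written by [write_modes()]
#'
#' @param path input file.
#' @param network the defining `metabolic_network` (column order is taken from
#'   the network).
#' @param format "tsv" or "json".
#' @return a `mode_set`.
#' @export
read_modes <- function(path, network, format = c("tsv", "json")) {
  format <- match.arg(format)
  rid <- network$reaction_ids
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    if (!all(rid %in% names(tab)))
      stop("mode TSV is missing reaction columns", call. = FALSE)
    k <- nrow(tab)
    num <- matrix(0, k, length(rid)); den <- matrix(1, k, length(rid))
    for (i in seq_len(k)) {
      p <- parse_rational(unlist(tab[i, rid], use.names = FALSE))
      num[i, ] <- p$num; den[i, ] <- p$den
    }
    rev <- vapply(seq_len(k), function(i)
      tab$mode_class[i] %in% RAY_CLASSES &&
        !any(which(num[i, ] != 0) %in% network$irr), logical(1))
    mode_set(num, den, classes = tab$mode_class, network = network,
             reversible = rev)
  } else {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    k <- length(x$modes)
    num <- matrix(0, k, length(rid)); den <- matrix(1, k, length(rid))
    classes <- character(k); rev <- logical(k)
    for (i in seq_len(k)) {
      p <- parse_rational(unlist(x$modes[[i]]$coeffs, use.names = FALSE))
      num[i, ] <- p$num; den[i, ] <- p$den
      classes[i] <- x$modes[[i]]$mode_class
      rev[i] <- isTRUE(x$modes[[i]]$reversible)
    }
    mode_set(num, den, classes = classes, network = network, reversible = rev)
  }
}
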