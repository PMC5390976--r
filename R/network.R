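# Metabolic network and constraint-set data model plus file dialects.
#
# A network is the stoichiometric matrix N (m internal metabolites x n
# reactions, exact rationals) together with the set Irr of irreversible
# reactions. External metabolites are represented by omission: they do not
# appear as rows of N. Inhomogeneous constraints are stored in the canonical
# ">=" form G r >= h with one provenance tag per row.

#' Construct a metabolic network
#'
#' @param metabolite_ids character vector of internal metabolite identifiers.
#' @param reaction_ids character vector of reaction identifiers.
#' @param stoich m x n matrix of net stoichiometric coefficients; numeric or
#'   character entries, parsed to exact rationals (decimal strings are read by
#'   decimal interpretation, "p/q" fractions are accepted).
#' @param irreversible reaction ids (or integer indices) of the irreversible
#'   reactions.
#' @return an object of class `metabolic_network` with components
#'   `metabolite_ids`, `reaction_ids`, `N_num`/`N_den` (exact stoichiometry)
#'   and `irr` (integer indices into `reaction_ids`).
#' @export
metabolic_network <- function(metabolite_ids, reaction_ids, stoich,
                              irreversible = character(0)) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (length(reaction_ids) == 0)
    stop("network must contain at least one reaction", call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite identifiers", call. = FALSE)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction identifiers", call. = FALSE)
  stoich <- as.matrix(stoich)
  if (nrow(stoich) != length(metabolite_ids) ||
      ncol(stoich) != length(reaction_ids))
    stop("stoichiometric matrix dimensions do not match identifier lists",
         call. = FALSE)
  r <- parse_rational(as.vector(stoich))
  m <- length(metabolite_ids); n <- length(reaction_ids)
  dn <- list(metabolite_ids, reaction_ids)
  if (is.numeric(irreversible)) {
    irr <- as.integer(irreversible)
    if (length(irr) && (min(irr) < 1 || max(irr) > n))
      stop("irreversible index out of range", call. = FALSE)
  } else {
    irr <- match(as.character(irreversible), reaction_ids)
    if (anyNA(irr))
      stop("unknown irreversible reaction id", call. = FALSE)
  }
  structure(list(
    metabolite_ids = metabolite_ids,
    reaction_ids = reaction_ids,
    N_num = matrix(r$num, m, n, dimnames = dn),
    N_den = matrix(r$den, m, n, dimnames = dn),
    irr = sort(unique(irr))
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", length(x$metabolite_ids), "internal metabolites,",
      length(x$reaction_ids), "reactions,",
      length(x$irr), "irreversible\n")
  invisible(x)
}

n_reactions <- function(network) length(network$reaction_ids)

# integer-scaled stoichiometric matrix (row scaling, exact)
network_int_N <- function(network) {
  if (nrow(network$N_num) == 0)
    return(matrix(0, 0, n_reactions(network)))
  int_scale_rows(network$N_num, network$N_den)$mat
}

#' Read a metabolic network from file
#'
#' Supported dialects:
#' \describe{
#'   \item{json}{`{"metabolites":[{"id","external"}],
#'     "reactions":[{"id","stoich":{met:coeff},"reversible"}]}`.}
#'   \item{tsv}{columns `reaction_id`, `equation` (e.g. `"x_S = A"`),
#'     `reversible` (0/1); metabolites prefixed `x_` are external.}
#'   \item{sbml}{SBML Level 3, read-only; boundary-condition species map to
#'     external metabolites and the `reversible` flag to the irreversible set.}
#' }
#' External metabolites are omitted from the rows of N.
#'
#' @param path input file.
#' @param format one of "json", "tsv", "sbml".
#' @param import_bounds for SBML only: also return fbc flux bounds as a
#'   constraint set (off by default, so that the homogeneous flux cone and the
#'   bounded flux polyhedron stay distinct objects).
#' @return a `metabolic_network`; for SBML with `import_bounds = TRUE`, a list
#'   with elements `network` and `constraints`.
#' @export
read_network <- function(path, format = c("json", "tsv", "sbml"),
                         import_bounds = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         json = .read_network_json(path),
         tsv = .read_network_tsv(path),
         sbml = .read_network_sbml(path, import_bounds))
}

.assemble_network <- function(met_ids, external, rxns) {
  # rxns: list of list(id, stoich = named character/numeric, reversible)
  if (!length(rxns)) stop("empty reaction list", call. = FALSE)
  internal <- met_ids[!external]
  rids <- vapply(rxns, function(r) r$id, character(1))
  if (anyDuplicated(rids)) stop("duplicate reaction identifiers", call. = FALSE)
  m <- length(internal); n <- length(rids)
  S <- matrix("0", m, n)
  for (j in seq_len(n)) {
    st <- rxns[[j]]$stoich
    for (met in names(st)) {
      if (!met %in% met_ids)
        stop("reaction ", rids[j], " references unknown metabolite ", met,
             call. = FALSE)
      i <- match(met, internal)
      if (!is.na(i)) S[i, j] <- as.character(st[[met]])
    }
  }
  irr <- rids[!vapply(rxns, function(r) isTRUE(r$reversible), logical(1))]
  metabolic_network(internal, rids, S, irr)
}

.read_network_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$metabolites) || is.null(x$reactions))
    stop("network JSON must contain 'metabolites' and 'reactions'",
         call. = FALSE)
  met_ids <- vapply(x$metabolites, function(m) m$id, character(1))
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite identifiers", call. = FALSE)
  external <- vapply(x$metabolites, function(m) isTRUE(m$external), logical(1))
  rxns <- lapply(x$reactions, function(r)
    list(id = r$id,
         stoich = lapply(r$stoich, function(v) v),
         reversible = isTRUE(r$reversible)))
  .assemble_network(met_ids, external, rxns)
}

# parse one side of a TSV equation ("2 A + B") into a named coefficient list
.parse_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(list())
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  out <- list()
  for (t in terms) {
    t <- trimws(t)
    toks <- strsplit(t, "[[:space:]]+")[[1]]
    if (length(toks) == 1) { coef <- "1"; met <- toks }
    else if (length(toks) == 2) { coef <- toks[1]; met <- toks[2] }
    else stop("cannot parse equation term '", t, "'", call. = FALSE)
    out[[met]] <- if (is.null(out[[met]])) coef else
      stop("metabolite repeated on one side of an equation", call. = FALSE)
  }
  out
}

.read_network_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("reaction_id", "equation", "reversible")
  if (!all(need %in% names(tab)))
    stop("network TSV requires columns reaction_id, equation, reversible",
         call. = FALSE)
  if (nrow(tab) == 0) stop("empty reaction list", call. = FALSE)
  rxns <- vector("list", nrow(tab))
  mets <- character(0)
  for (j in seq_len(nrow(tab))) {
    sides <- strsplit(tab$equation[j], "=", fixed = TRUE)[[1]]
    if (length(sides) != 2)
      stop("equation must contain exactly one '=': ", tab$equation[j],
           call. = FALSE)
    lhs <- .parse_side(sides[1]); rhs <- .parse_side(sides[2])
    st <- list()
    for (met in names(lhs)) st[[met]] <- paste0("-", lhs[[met]])
    for (met in names(rhs)) {
      if (!is.null(st[[met]])) {
        r <- rat_sub(parse_rational(rhs[[met]])$num,
                     parse_rational(rhs[[met]])$den,
                     -parse_rational(st[[met]])$num,
                     parse_rational(st[[met]])$den)
        st[[met]] <- format_rational(r$num, r$den)
      } else st[[met]] <- rhs[[met]]
    }
    mets <- union(mets, names(st))
    rxns[[j]] <- list(id = tab$reaction_id[j], stoich = st,
                      reversible = tab$reversible[j] %in% c("1", "true", "TRUE"))
  }
  .assemble_network(mets, startsWith(mets, "x_"), rxns)
}

#' Write a metabolic network to file
#'
#' Inverse of [read_network()] for the json and tsv dialects; round-trips are
#' exact. External metabolites carry the `x_` prefix in the tsv dialect and
#' are reconstructed as `external: true` entries in json (the network object
#' itself stores only internal metabolites, so none are emitted here).
#'
#' @param network a `metabolic_network`.
#' @param path output file.
#' @param format "json" or "tsv".
#' @export
write_network <- function(network, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  n <- n_reactions(network)
  irr <- seq_len(n) %in% network$irr
  if (format == "json") {
    mets <- lapply(network$metabolite_ids, function(id)
      list(id = id, external = FALSE))
    rxns <- lapply(seq_len(n), function(j) {
      nz <- which(network$N_num[, j] != 0)
      st <- as.list(format_rational(network$N_num[nz, j], network$N_den[nz, j]))
      names(st) <- network$metabolite_ids[nz]
      list(id = network$reaction_ids[j], stoich = st, reversible = !irr[j])
    })
    jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    eqs <- vapply(seq_len(n), function(j) {
      nz <- which(network$N_num[, j] != 0)
      co <- format_rational(network$N_num[nz, j], network$N_den[nz, j])
      neg <- network$N_num[nz, j] < 0
      term <- function(i, flip) {
        c_abs <- format_rational(abs(network$N_num[nz, j][i]),
                                 network$N_den[nz, j][i])
        met <- network$metabolite_ids[nz][i]
        if (c_abs == "1") met else paste(c_abs, met)
      }
      lhs <- paste(vapply(which(neg), term, character(1), flip = TRUE),
                   collapse = " + ")
      rhs <- paste(vapply(which(!neg), term, character(1), flip = FALSE),
                   collapse = " + ")
      paste(lhs, "=", rhs)
    }, character(1))
    tab <- data.frame(reaction_id = network$reaction_ids, equation = eqs,
                      reversible = as.integer(!irr))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

# ---- SBML (Level 3, read-only) ---------------------------------------------

.read_network_sbml <- function(path, import_bounds = FALSE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(sp, "id")
  external <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(xml2::xml_attr(params, "value"),
                          xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rnodes, function(rn) {
    st <- list()
    for (s in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      met <- xml2::xml_attr(s, "species")
      coef <- xml2::xml_attr(s, "stoichiometry"); if (is.na(coef)) coef <- "1"
      st[[met]] <- paste0("-", coef)
    }
    for (s in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      met <- xml2::xml_attr(s, "species")
      coef <- xml2::xml_attr(s, "stoichiometry"); if (is.na(coef)) coef <- "1"
      st[[met]] <- coef
    }
    list(id = xml2::xml_attr(rn, "id"), stoich = st,
         reversible = xml2::xml_attr(rn, "reversible") %in% c("true", "1"))
  })
  network <- .assemble_network(met_ids, external, rxns)
  if (!import_bounds) return(network)
  bounds <- list()
  for (rn in rnodes) {
    id <- xml2::xml_attr(rn, "id")
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else NA
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else NA
    if (!is.na(lb) || !is.na(ub))
      bounds[[id]] <- list(lb = if (is.na(lb)) NULL else lb,
                           ub = if (is.na(ub)) NULL else ub)
  }
  list(network = network, constraints = build_constraints(network, bounds))
}

# ---- constraint sets -------------------------------------------------------

.is_unbounded <- function(v) is.null(v) || (is.numeric(v) && is.infinite(v)) ||
  (length(v) == 1 && is.na(v))

#' Assemble an inhomogeneous constraint set G r >= h
#'
#' Finite flux bounds and general linear rows are converted to canonical
#' ">=" form: an upper bound `r_i <= u` is stored as `-e_i . r >= -u`, a lower
#' bound as `e_i . r >= l`, a "<=" row is negated, and each "=" row yields two
#' rows with negated coefficients and right-hand sides (tagged as the two
#' halves of one equality). Infinite/missing bounds contribute no row.
#'
#' @param network a `metabolic_network`.
#' @param bounds named list: reaction id -> list(lb =, ub =) (either may be
#'   omitted, `NULL`, `NA` or infinite for "no bound"); values are parsed as
#'   exact rationals.
#' @param rows list of general constraints, each
#'   `list(coeffs = named list, sense = ">="|"<="|"=", rhs =)`.
#' @return an object of class `constraint_set` with exact `G_num`/`G_den`,
#'   `h_num`/`h_den`, per-row `tags`, and the reaction ids it refers to.
#' @export
build_constraints <- function(network, bounds = list(), rows = list()) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- n_reactions(network)
  rid <- network$reaction_ids
  Gn <- matrix(0, 0, n); Gd <- matrix(1, 0, n)
  hn <- numeric(0); hd <- numeric(0); tags <- character(0)
  add_row <- function(gn, gd, rn, rd, tag) {
    Gn <<- rbind(Gn, gn); Gd <<- rbind(Gd, gd)
    hn <<- c(hn, rn); hd <<- c(hd, rd); tags <<- c(tags, tag)
  }
  unknown <- setdiff(names(bounds), rid)
  if (length(unknown))
    stop("unknown reaction id in bounds: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (j in seq_len(n)) {
    b <- bounds[[rid[j]]]
    if (is.null(b)) next
    lb <- b$lb; ub <- b$ub
    has_lb <- !.is_unbounded(lb); has_ub <- !.is_unbounded(ub)
    if (has_lb) lb <- parse_rational(lb)
    if (has_ub) ub <- parse_rational(ub)
    if (has_lb && has_ub &&
        rat_cmp(lb$num, lb$den, ub$num, ub$den) > 0)
      stop("inconsistent bounds for ", rid[j], ": lb > ub", call. = FALSE)
    e <- numeric(n); d <- rep(1, n)
    if (has_lb) {
      e[j] <- 1
      add_row(e, d, lb$num, lb$den, paste0("lower_bound:", rid[j]))
      e[j] <- 0
    }
    if (has_ub) {
      e[j] <- -1
      add_row(e, d, -ub$num, ub$den, paste0("upper_bound:", rid[j]))
    }
  }
  eq_k <- 0
  for (row in rows) {
    cf <- row$coeffs
    unknown <- setdiff(names(cf), rid)
    if (length(unknown))
      stop("unknown reaction id in constraint row: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    gn <- numeric(n); gd <- rep(1, n)
    for (r in names(cf)) {
      p <- parse_rational(cf[[r]])
      j <- match(r, rid)
      gn[j] <- p$num; gd[j] <- p$den
    }
    rhs <- parse_rational(row$rhs)
    sense <- row$sense
    if (sense == ">=") {
      add_row(gn, gd, rhs$num, rhs$den, "general")
    } else if (sense == "<=") {
      add_row(-gn, gd, -rhs$num, rhs$den, "general")
    } else if (sense == "=") {
      eq_k <- eq_k + 1
      add_row(gn, gd, rhs$num, rhs$den, paste0("equality_half:", eq_k))
      add_row(-gn, gd, -rhs$num, rhs$den, paste0("equality_half:", eq_k))
    } else stop("sense must be one of '>=', '<=', '='", call. = FALSE)
  }
  structure(list(G_num = Gn, G_den = Gd, h_num = hn, h_den = hd,
                 tags = tags, reaction_ids = rid),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint_set:", length(x$h_num), "rows over",
      length(x$reaction_ids), "reactions\n")
  invisible(x)
}

n_constraint_rows <- function(constraints) {
  if (is.null(constraints)) 0L else length(constraints$h_num)
}

# empty constraint set (pure flux-cone case)
empty_constraints <- function(network) build_constraints(network)

#' Read a constraint set from JSON
#'
#' Dialect: `{"bounds":{rxn:{"lb":num|null,"ub":num|null}},
#' "rows":[{"coeffs":{rxn:coeff},"sense":">=|<=|=","rhs":num}]}`.
#'
#' @param network the target `metabolic_network`.
#' @param path JSON file.
#' @return a `constraint_set`.
#' @export
read_constraints <- function(network, path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bounds <- if (is.null(x$bounds)) list() else x$bounds
  rows <- if (is.null(x$rows)) list() else x$rows
  build_constraints(network, bounds, rows)
}
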