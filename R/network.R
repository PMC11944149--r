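#' @keywords internal
"_PACKAGE"

# Condition helpers used across the package: config errors (exit code 2 at the
# CLI), infeasibility errors (exit 3), I/O errors (exit 4).
stop_config <- function(...) {
  stop(structure(class = c("entroflux_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_infeasible <- function(...) {
  stop(structure(class = c("entroflux_infeasible", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_io <- function(...) {
  stop(structure(class = c("entroflux_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Parse a plain-text metabolic reaction list
#'
#' Reads the package's reaction-list dialect: one reaction per line,
#' \code{"id: 1 a + 2 b => c"} for an irreversible reaction or \code{"<=>"}
#' for a reversible one. Omitted coefficients default to 1. Metabolites whose
#' id carries the external suffix (default \code{".Ext"}) cross the system
#' boundary and are excluded from the steady-state constraint; further ids can
#' be declared external explicitly via \code{external_ids}. Blank lines and
#' lines starting with \code{#} are ignored.
#'
#' A metabolite id appearing both with and without the suffix (e.g.
#' \code{glc.Ext} and \code{glc}) denotes two distinct species, the external
#' pool and its internal counterpart; such pairs are reported with a message.
#'
#' When a proton-balance reaction (default id \code{"v74"}) is present in the
#' network, the proton species (default \code{"h"}) still participates in
#' reaction stoichiometries but is dropped from the steady-state constraint,
#' since the balance reaction closes it by construction.
#'
#' @param text character vector of lines, or a single string containing
#'   newlines, or a file path (when \code{is_file = TRUE}).
#' @param external_suffix suffix marking external metabolites.
#' @param external_ids additional metabolite ids treated as external.
#' @param proton_id metabolite id of the proton species.
#' @param proton_balance_reaction reaction id whose presence triggers the
#'   exclusion of \code{proton_id} from the steady-state constraint.
#' @param is_file read \code{text} as a file path.
#' @return a \code{reaction_network} object: metabolite table, reaction table
#'   (with stoichiometry stored as named numeric vectors), and the internal
#'   stoichiometric matrix \code{S_int}.
#' @examples
#' net <- parse_reaction_list(c(
#'   "v1: glc.Ext => glc",
#'   "v2: glc => 2 pyr",
#'   "v3: pyr => pyr.Ext"))
#' stoichiometric_matrix(net)
#' @export
parse_reaction_list <- function(text, external_suffix = ".Ext",
                                external_ids = character(),
                                proton_id = "h",
                                proton_balance_reaction = "v74",
                                is_file = FALSE) {
  if (is_file) {
    if (!file.exists(text)) stop_io("reaction list file not found: ", text)
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  ids <- character(0)
  reversible <- logical(0)
  stoich <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    m <- regmatches(raw, regexec("^([^:[:space:]]+)\\s*:\\s*(.*)$", raw))[[1]]
    if (length(m) != 3L)
      stop("unparseable reaction line ", ln, ": ", raw)
    id <- m[[2]]
    body <- m[[3]]
    rev <- grepl("<=>", body, fixed = TRUE)
    sides <- strsplit(body, if (rev) "<=>" else "=>", fixed = TRUE)[[1]]
    if (length(sides) != 2L)
      stop("unparseable reaction line ", ln, " (missing arrow): ", raw)
    if (id %in% ids)
      stop("duplicate reaction id '", id, "' at line ", ln)
    st <- numeric(0)
    for (side in 1:2) {
      sgn <- if (side == 1L) -1 else 1
      terms <- strsplit(sides[[side]], "+", fixed = TRUE)[[1]]
      for (term in terms) {
        term <- trimws(term)
        if (term == "") next
        tm <- regmatches(term,
          regexec("^([0-9]*\\.?[0-9]+)?\\s*([^[:space:]]+)$", term))[[1]]
        if (length(tm) != 3L || tm[[3]] == "")
          stop("unparseable term '", term, "' at line ", ln)
        coeff <- if (tm[[2]] == "") 1 else as.numeric(tm[[2]])
        met <- tm[[3]]
        st[met] <- (if (met %in% names(st)) st[[met]] else 0) + sgn * coeff
      }
    }
    st <- st[st != 0]
    if (length(st) == 0L)
      stop("reaction '", id, "' at line ", ln, " has empty net stoichiometry")
    ids <- c(ids, id)
    reversible <- c(reversible, rev)
    stoich <- c(stoich, list(st))
  }
  mets <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  external <- endsWith(mets, external_suffix) | mets %in% external_ids
  # report internal/external sibling pairs (distinct species by design)
  base_of_ext <- sub(paste0("\\Q", external_suffix, "\\E$"), "",
                     mets[endsWith(mets, external_suffix)])
  pairs <- intersect(base_of_ext, mets)
  if (length(pairs))
    message("treating suffixed/unsuffixed ids as distinct species: ",
            paste0(pairs, "/", pairs, external_suffix, collapse = ", "))
  reaction_network(
    metabolites = data.frame(id = mets, external = external,
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = ids, reversible = reversible,
                           stringsAsFactors = FALSE),
    stoich = stoich,
    proton_id = proton_id,
    proton_balance_reaction = proton_balance_reaction,
    external_suffix = external_suffix)
}

#' Construct a validated reaction network
#'
#' Lower-level constructor behind [parse_reaction_list()]. Validates reaction
#' id uniqueness and nonempty stoichiometries, and builds the full and
#' internal stoichiometric matrices.
#'
#' @param metabolites data.frame with columns \code{id}, \code{external}.
#' @param reactions data.frame with columns \code{id}, \code{reversible}.
#' @param stoich list (one per reaction) of named numeric vectors.
#' @param proton_id,proton_balance_reaction see [parse_reaction_list()].
#' @param external_suffix suffix recorded for serialization.
#' @return a \code{reaction_network} object.
#' @export
reaction_network <- function(metabolites, reactions, stoich,
                             proton_id = "h",
                             proton_balance_reaction = "v74",
                             external_suffix = ".Ext") {
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id")
  if (length(stoich) != nrow(reactions))
    stop("stoich list length must match number of reactions")
  if (any(vapply(stoich, length, 1L) == 0L))
    stop("every reaction needs at least one nonzero coefficient")
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (k in seq_along(stoich)) S[names(stoich[[k]]), k] <- stoich[[k]]
  exclude <- metabolites$external
  if (proton_balance_reaction %in% reactions$id && proton_id %in% metabolites$id)
    exclude <- exclude | metabolites$id == proton_id
  net <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich,
    S_full = S,
    S_int = S[!exclude, , drop = FALSE],
    proton_id = proton_id,
    proton_balance_reaction = proton_balance_reaction,
    external_suffix = external_suffix), class = "reaction_network")
  net
}

#' Internal stoichiometric matrix of a network
#'
#' Rows are the metabolites subject to the steady-state constraint (internal
#' metabolites, minus the proton species when a proton-balance reaction is
#' present), columns are reactions, both in input order.
#'
#' @param network a \code{reaction_network}.
#' @param internal_only return only the constrained rows (default); otherwise
#'   the full metabolite-by-reaction matrix.
#' @return numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(network, internal_only = TRUE) {
  if (internal_only) network$S_int else network$S_full
}

#' External stoichiometric matrix (boundary metabolites by reactions)
#' @param network a \code{reaction_network}.
#' @return numeric matrix over external metabolites.
#' @export
external_matrix <- function(network) {
  network$S_full[network$metabolites$external, , drop = FALSE]
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites (",
      sum(x$metabolites$external), "external )\n")
  cat("  reversible:", sum(x$reactions$reversible), "\n")
  if (nrow(x$S_int) < nrow(x$S_full) - sum(x$metabolites$external))
    cat("  proton '", x$proton_id, "' excluded from steady-state constraint\n",
        sep = "")
  invisible(x)
}

#' Serialize a network back to the reaction-list dialect
#'
#' Inverse of [parse_reaction_list()] on the canonical dialect:
#' parse-serialize-parse is the identity.
#'
#' @param network a \code{reaction_network}.
#' @return character vector of lines.
#' @export
format_reaction_list <- function(network) {
  fmt_side <- function(st) {
    paste(vapply(names(st), function(m) {
      co <- st[[m]]
      if (co == 1) m else paste(format(co, scientific = FALSE, trim = TRUE), m)
    }, ""), collapse = " + ")
  }
  vapply(seq_len(nrow(network$reactions)), function(k) {
    st <- network$stoich[[k]]
    lhs <- -st[st < 0]
    rhs <- st[st > 0]
    arrow <- if (network$reactions$reversible[k]) "<=>" else "=>"
    paste0(network$reactions$id[k], ": ", fmt_side(lhs), " ", arrow, " ",
           fmt_side(rhs))
  }, "")
}

#' Parse a molecular formula string into element counts
#'
#' Handles fractional subscripts as used for biomass pseudo-species
#' (e.g. \code{"CH1.6N0.26O0.38P0.023S0.006"}).
#'
#' @param formula formula string over elements C,H,N,O,P,S.
#' @return named numeric vector of element counts over C,H,N,O,P,S.
#' @export
parse_formula <- function(formula) {
  out <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  if (is.na(formula) || formula == "") return(out)
  pat <- "([CHNOPS])([0-9]*\\.?[0-9]*)"
  ms <- regmatches(formula, gregexpr(pat, formula))[[1]]
  if (paste(ms, collapse = "") != gsub("\\s", "", formula))
    stop("cannot parse formula: ", formula)
  for (tok in ms) {
    el <- substr(tok, 1, 1)
    n <- substring(tok, 2)
    out[[el]] <- out[[el]] + if (n == "") 1 else as.numeric(n)
  }
  out
}

#' Per-reaction elemental balance report
#'
#' For each reaction, the signed imbalance of each element in C,H,N,O,P,S:
#' the element content of products minus reactants. A zero row means the
#' reaction is elementally balanced. Reactions involving a metabolite with no
#' formula are flagged uncheckable rather than raising an error.
#'
#' @param network a \code{reaction_network}.
#' @param formulas named list/vector of formula strings (or named numeric
#'   element-count vectors) keyed by metabolite id.
#' @return data.frame: reaction id, checkable flag, one column per element,
#'   and \code{balanced}.
#' @export
elemental_balance_report <- function(network, formulas) {
  els <- c("C", "H", "N", "O", "P", "S")
  fmat <- matrix(NA_real_, nrow(network$metabolites), 6,
                 dimnames = list(network$metabolites$id, els))
  for (m in names(formulas)) {
    if (!m %in% rownames(fmat)) next
    f <- formulas[[m]]
    if (is.character(f)) f <- parse_formula(f)
    fmat[m, ] <- f[els]
  }
  res <- data.frame(reaction = network$reactions$id,
                    checkable = NA, stringsAsFactors = FALSE)
  for (el in els) res[[el]] <- NA_real_
  for (k in seq_len(nrow(res))) {
    st <- network$stoich[[k]]
    rows <- fmat[names(st), , drop = FALSE]
    if (anyNA(rows)) { res$checkable[k] <- FALSE; next }
    res$checkable[k] <- TRUE
    res[k, els] <- as.numeric(st %*% rows)
  }
  res$balanced <- res$checkable &
    apply(abs(as.matrix(res[, els])), 1, max) < 1e-9
  res$balanced[!res$checkable] <- NA
  res
}

#' Write the internal stoichiometric matrix as TSV
#' @param network a \code{reaction_network}.
#' @param path output file path.
#' @export
write_stoichiometric_matrix <- function(network, path) {
  S <- stoichiometric_matrix(network)
  df <- data.frame(metabolite = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
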