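# Elementary flux mode enumeration (binary nullspace / Schuster tableau with
# support-minimality pruning) and mode-set utilities.

.support <- function(v, tol = 1e-9) abs(v) > tol

# Keep only support-minimal rows of a nonnegative ray matrix; also drops
# duplicate supports (rays with equal support are positive multiples of each
# other at this stage of the tableau).
.prune_minimal <- function(R, tol = 1e-9) {
  if (nrow(R) <= 1L) return(R)
  supp <- abs(R) > tol
  sizes <- rowSums(supp)
  ord <- order(sizes)
  keep <- rep(TRUE, nrow(R))
  suppl <- lapply(seq_len(nrow(R)), function(i) which(supp[i, ]))
  for (a in seq_along(ord)) {
    i <- ord[[a]]
    if (!keep[i]) next
    si <- suppl[[i]]
    for (b in seq_along(ord)) {
      if (b == a) next
      j <- ord[[b]]
      if (!keep[j] || sizes[j] < sizes[i]) next
      if (all(si %in% suppl[[j]]) && (sizes[j] > sizes[i] || b > a))
        keep[j] <- FALSE
    }
  }
  R[keep, , drop = FALSE]
}

#' Enumerate elementary flux modes of a reaction network
#'
#' Implements the classical tableau (double-description on the flux cone after
#' splitting reversible reactions into forward/backward halves): metabolite
#' constraints are imposed one at a time, combining positive/negative ray
#' pairs and discarding rays whose support strictly contains another ray's
#' support. Trivial two-cycles created by splitting a reversible reaction are
#' removed, the halves are recombined into signed net fluxes, and modes that
#' are sign-reversals of each other (possible only on fully reversible
#' support) are deduplicated. The result is ordered lexicographically by
#' reaction support and each mode is scaled so its largest absolute flux is 1.
#'
#' @param network a \code{reaction_network}.
#' @param max_candidates guard against combinatorial blow-up: the tableau
#'   aborts with an error if the candidate count ever exceeds this cap.
#' @param tol numeric tolerance for zero tests.
#' @return an \code{efm_set}: \code{fluxes} (modes-by-reactions matrix),
#'   \code{external} (modes-by-external-metabolites net stoichiometry),
#'   plus bookkeeping fields.
#' @examples
#' net <- toy_network("diamond")
#' enumerate_modes(net)$n
#' @export
enumerate_modes <- function(network, max_candidates = 200000L, tol = 1e-9) {
  S <- stoichiometric_matrix(network)
  rev <- network$reactions$reversible
  rxn <- network$reactions$id
  q0 <- length(rxn)
  # split reversible reactions: columns fwd(all) then bwd(reversible only)
  Ssplit <- cbind(S, -S[, rev, drop = FALSE])
  split_origin <- c(seq_len(q0), which(rev))
  split_sign <- c(rep(1, q0), rep(-1, sum(rev)))
  q <- ncol(Ssplit)
  R <- diag(q)
  for (i in seq_len(nrow(Ssplit))) {
    w <- as.numeric(R %*% Ssplit[i, ])
    zero <- abs(w) <= tol
    pos <- which(w > tol)
    neg <- which(w < -tol)
    if (length(pos) * length(neg) + sum(zero) > max_candidates)
      stop("elementary-mode candidate count exceeds max_candidates (",
           max_candidates, "); raise the cap to proceed")
    news <- NULL
    if (length(pos) && length(neg)) {
      news <- matrix(0, length(pos) * length(neg), q)
      r <- 1L
      for (a in pos) for (b in neg) {
        v <- w[a] * R[b, ] - w[b] * R[a, ]
        news[r, ] <- v / max(abs(v))
        r <- r + 1L
      }
    }
    R <- rbind(R[zero, , drop = FALSE], news)
    if (nrow(R) == 0L) break
    R <- .prune_minimal(R, tol)
  }
  if (nrow(R)) {
    # drop the trivial fwd+bwd two-cycles of split reversible reactions
    is_twocycle <- vapply(seq_len(nrow(R)), function(j) {
      s <- which(.support(R[j, ], tol))
      length(s) == 2L && split_origin[s[1]] == split_origin[s[2]]
    }, NA)
    R <- R[!is_twocycle, , drop = FALSE]
  }
  # recombine split halves into signed fluxes on the original reactions
  V <- matrix(0, nrow(R), q0, dimnames = list(NULL, rxn))
  for (c0 in seq_len(q)) V[, split_origin[c0]] <- V[, split_origin[c0]] +
    split_sign[c0] * R[, c0]
  V <- .dedupe_sign_reversals(V, rev, tol)
  .efm_set(V, network, tol)
}

.dedupe_sign_reversals <- function(V, rev, tol = 1e-9) {
  if (nrow(V) < 2L) return(V)
  # a mode supported only on reversible reactions appears in both directions;
  # keep the representative whose first nonzero flux is positive
  keep <- rep(TRUE, nrow(V))
  keys <- apply(.support(V, tol), 1, function(s) paste(which(s), collapse = ","))
  for (key in unique(keys[duplicated(keys)])) {
    idx <- which(keys == key & keep)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a >= b || !keep[a] || !keep[b]) next
      va <- V[a, ] / max(abs(V[a, ])); vb <- V[b, ] / max(abs(V[b, ]))
      if (max(abs(va + vb)) < 1e-6) {
        drop_a <- va[which(.support(va, tol))[1]] < 0
        keep[if (drop_a) a else b] <- FALSE
      }
    }
  }
  V[keep, , drop = FALSE]
}

# Assemble an efm_set from a modes-by-reactions flux matrix.
.efm_set <- function(V, network, tol = 1e-9, validate = TRUE) {
  if (nrow(V)) {
    scal <- apply(abs(V), 1, max)
    V <- V / scal
    # lexicographic order by support pattern
    supp <- .support(V, tol)
    key <- apply(supp, 1, function(s) paste(sprintf("%04d", which(s)),
                                            collapse = ","))
    V <- V[order(key), , drop = FALSE]
  }
  S_int <- stoichiometric_matrix(network)
  if (validate && nrow(V)) {
    resid <- max(abs(V %*% t(S_int)))
    if (resid > 1e-7)
      stop("internal error: mode violates steady state (residual ", resid, ")")
  }
  ext <- external_matrix(network)
  EX <- if (nrow(V)) V %*% t(ext) else
    matrix(0, 0, nrow(ext), dimnames = list(NULL, rownames(ext)))
  rownames(V) <- rownames(EX) <- if (nrow(V)) paste0("m", seq_len(nrow(V)))
  structure(list(fluxes = V, external = EX,
                 reaction_ids = colnames(V),
                 reversible = network$reactions$reversible,
                 network_ref = paste(network$reactions$id, collapse = "|"),
                 n = nrow(V), normalized = FALSE,
                 nonglucose = NULL, glucose_id = NULL),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  cat("efm_set:", x$n, "elementary modes over", length(x$reaction_ids),
      "reactions\n")
  if (x$normalized)
    cat("  normalized to 1 mol", x$glucose_id,
        if (!is.null(x$nonglucose)) paste0("(", nrow(x$nonglucose$fluxes),
                                           " non-glucose modes segregated)"),
        "\n")
  invisible(x)
}

#' Normalize a mode set to one mole of glucose consumed
#'
#' Scales every mode so that its net coefficient on the external glucose
#' species is exactly -1. Modes with zero net glucose uptake (e.g. futile
#' cycles) are segregated into a \code{nonglucose} subset and excluded from
#' the main set (and hence from any downstream Boltzmann fit).
#'
#' @param modes an \code{efm_set}.
#' @param glucose_id external glucose metabolite id.
#' @param tol zero tolerance for glucose uptake.
#' @return the normalized \code{efm_set}.
#' @export
normalize_to_glucose <- function(modes, glucose_id = "glc.Ext", tol = 1e-9) {
  if (!glucose_id %in% colnames(modes$external))
    stop_config("glucose id '", glucose_id, "' is not an external metabolite")
  g <- modes$external[, glucose_id]
  zero <- abs(g) <= tol
  if (any(g > tol))
    stop_infeasible("mode(s) ", paste(which(g > tol), collapse = ","),
                    " produce rather than consume glucose")
  out <- modes
  if (any(zero)) {
    out$nonglucose <- list(fluxes = modes$fluxes[zero, , drop = FALSE],
                           external = modes$external[zero, , drop = FALSE])
    out$fluxes <- modes$fluxes[!zero, , drop = FALSE]
    out$external <- modes$external[!zero, , drop = FALSE]
    g <- g[!zero]
  }
  scal <- -1 / g
  out$fluxes <- out$fluxes * scal
  out$external <- out$external * scal
  out$external[, glucose_id] <- -1  # exact by construction
  out$n <- nrow(out$fluxes)
  out$normalized <- TRUE
  out$glucose_id <- glucose_id
  out
}

#' Write a mode matrix as TSV (modes as rows, reactions as columns)
#' @param modes an \code{efm_set}.
#' @param path output path.
#' @export
write_modes <- function(modes, path) {
  df <- data.frame(mode = rownames(modes$fluxes), modes$fluxes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a precomputed mode matrix
#'
#' Reads a delimited mode matrix (one row per mode; columns matched to the
#' network's reaction ids by header name, so column permutations are
#' harmless). Every row is validated against the steady-state constraint and
#' the irreversibility sign pattern; offending rows are rejected with their
#' row index.
#'
#' @param table a file path or a data.frame/matrix with reaction-id columns
#'   (an optional leading \code{mode} label column is ignored).
#' @param network the \code{reaction_network} the modes belong to.
#' @param tol steady-state tolerance.
#' @return an \code{efm_set}.
#' @export
import_modes <- function(table, network, tol = 1e-9) {
  if (is.character(table)) {
    if (!file.exists(table)) stop_io("mode matrix file not found: ", table)
    table <- utils::read.table(table, header = TRUE, sep = "\t",
                               check.names = FALSE)
  }
  tab <- as.data.frame(table, check.names = FALSE)
  tab <- tab[, setdiff(colnames(tab), "mode"), drop = FALSE]
  rxn <- network$reactions$id
  missing <- setdiff(rxn, colnames(tab))
  extra <- setdiff(colnames(tab), rxn)
  if (length(missing) || length(extra))
    stop_config("mode matrix columns do not match network reactions",
                if (length(missing)) paste0("; missing: ",
                                            paste(missing, collapse = ",")),
                if (length(extra)) paste0("; unknown: ",
                                          paste(extra, collapse = ",")))
  V <- as.matrix(tab[, rxn, drop = FALSE])
  S_int <- stoichiometric_matrix(network)
  scal <- pmax(apply(abs(V), 1, max), .Machine$double.eps)
  resid <- apply(abs((V / scal) %*% t(S_int)), 1, max)
  bad_ss <- which(resid > tol * 100)
  irrev <- !network$reactions$reversible
  bad_sign <- which(apply(V[, irrev, drop = FALSE] < -tol, 1, any))
  bad <- sort(union(bad_ss, bad_sign))
  if (length(bad))
    stop_infeasible("rejected mode rows ", paste(bad, collapse = ","),
                    ": violate steady state or irreversibility")
  .efm_set(V, network, tol)
}
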