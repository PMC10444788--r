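#' Residue-ligand contact frequencies over a trajectory
#'
#' A residue is in contact with the ligand in a frame iff any of its heavy
#' atoms lies within `cutoff` of any ligand heavy atom; its frequency is the
#' fraction of frames in contact. The residue universe is every non-ligand
#' residue of the topology except waters and (by default) common membrane
#' lipids; the distance criterion deliberately aggregates all interaction
#' types into one reproducible geometric rule, with the cutoff recorded in
#' the output.
#'
#' @param traj a `Trajectory`.
#' @param ligand `Selection` of ligand atoms (hydrogens are dropped).
#' @param cutoff contact distance cutoff, Angstrom (default 4.5).
#' @param exclude_resnames residue names excluded from the universe (waters
#'   plus common lipids by default).
#' @return object of class `ContactTable`: data frame (chain, resno, resid,
#'   frequency, n_contact_frames); attributes `cutoff`, `frames_counted`.
#' @export
contact_frequencies <- function(traj, ligand, cutoff = 4.5,
                                exclude_resnames = c(.water_resnames,
                                                     "POPC", "POPE", "POPS",
                                                     "CHL1")) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- n_frames(traj)
  if (nf == 0) stop("empty input: trajectory has no frames")
  top <- traj$topology
  lig <- ligand[top$element[ligand] != "H"]
  if (length(lig) == 0) stop("selection error: no ligand heavy atoms")
  env <- which(!(seq_len(nrow(top)) %in% lig) &
                 !(top$resid %in% exclude_resnames) & top$element != "H")
  if (length(env) == 0) stop("no environment residues in topology")
  res_key <- paste(top$chain[env], top$resno[env], sep = ":")
  keys <- unique(res_key)
  fac <- factor(res_key, levels = keys)
  hits <- setNames(integer(length(keys)), keys)
  cut2 <- cutoff^2
  for (i in seq_len(nf)) {
    fr <- traj$coords[, , i]
    E <- fr[env, , drop = FALSE]
    Lg <- fr[lig, , drop = FALSE]
    # min squared distance of each environment atom to the ligand
    mind2 <- rep(Inf, nrow(E))
    for (j in seq_len(nrow(Lg))) {
      d2 <- (E[, 1] - Lg[j, 1])^2 + (E[, 2] - Lg[j, 2])^2 +
        (E[, 3] - Lg[j, 3])^2
      sel <- d2 < mind2
      mind2[sel] <- d2[sel]
    }
    in_contact <- tapply(mind2 <= cut2, fac, any)
    hits <- hits + as.integer(in_contact)
  }
  first <- !duplicated(res_key)
  out <- data.frame(chain = top$chain[env][first],
                    resno = top$resno[env][first],
                    resid = top$resid[env][first],
                    frequency = as.numeric(hits[res_key[first]]) / nf,
                    n_contact_frames = as.integer(hits[res_key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, frames_counted = nf,
            class = c("ContactTable", "data.frame"))
}

#' Aggregate contact tables across simulation replicates
#'
#' Residue universes are unioned with zero-fill (a residue absent from one
#' replicate's table contributes frequency 0 there); per residue the sample
#' mean and sample standard deviation (n-1 denominator) across replicates
#' are reported.
#'
#' @param tables list of `ContactTable` objects (>= 2).
#' @return object of class `ContactSummary`: data frame (chain, resno, resid,
#'   mean, sd, n).
#' @export
summarize_replicates <- function(tables) {
  if (!is.list(tables) || length(tables) < 2)
    stop("degenerate input: need at least 2 replicate tables")
  lapply(tables, function(t) stopifnot(inherits(t, "ContactTable")))
  key_of <- function(t) paste(t$chain, t$resno, sep = ":")
  keys <- unique(unlist(lapply(tables, key_of)))
  n <- length(tables)
  freq <- matrix(0, length(keys), n, dimnames = list(keys, NULL))
  resid_map <- character(0)
  for (j in seq_len(n)) {
    t <- tables[[j]]
    k <- key_of(t)
    freq[k, j] <- t$frequency
    new <- setdiff(k, names(resid_map))
    resid_map[new] <- t$resid[match(new, k)]
  }
  resid <- unname(resid_map[keys])
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1),
    resno = as.integer(vapply(parts, `[`, "", 2)),
    resid = resid,
    mean = rowMeans(freq),
    sd = apply(freq, 1, sd),
    n = n, stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  structure(out, class = c("ContactSummary", "data.frame"))
}

#' Frequently contacted residues (the >= 50 percent rule)
#'
#' Residues whose mean contact frequency meets the threshold (inclusive),
#' sorted by frequency descending, then residue number.
#'
#' @param summary a `ContactSummary` (or a `ContactTable`, in which case its
#'   single-replicate frequencies are used).
#' @param threshold inclusion threshold as a fraction (default 0.5).
#' @return data frame of the qualifying rows of `summary`.
#' @export
frequent_contacts <- function(summary, threshold = 0.5) {
  f <- if (inherits(summary, "ContactSummary")) summary$mean
       else if (inherits(summary, "ContactTable")) summary$frequency
       else stop("expected a ContactSummary or ContactTable")
  keep <- which(f >= threshold)
  out <- summary[keep[order(-f[keep], summary$resno[keep])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a contact table with prime indices
#' @param table a `ContactTable` or `ContactSummary`.
#' @param prime_map a `PrimeMap`.
#' @return the table with a `prime` column (NA where unmapped).
#' @export
annotate_primes <- function(table, prime_map) {
  key <- paste(table$chain, table$resno, sep = ":")
  pkey <- paste(prime_map$chain, prime_map$resno, sep = ":")
  table$prime <- prime_map$prime[match(key, pkey)]
  table
}
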