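#' Subunit map for a pentameric receptor
#'
#' Maps chain identifiers to subunit classes (`alpha`, `beta`, `gamma`) with a
#' copy index per class. For an alpha1-beta2-gamma2 heteropentamer the class
#' counts must be 2/2/1.
#'
#' @param chain_to_class named character vector, names = chain ids, values in
#'   `c("alpha","beta","gamma")`.
#' @param stoichiometry `"a1b2g2"` to enforce the 2 alpha / 2 beta / 1 gamma
#'   composition, or `"free"` to accept any pentamer.
#' @return object of class `SubunitMap` (data frame: chain, class, copy).
#' @export
subunit_map <- function(chain_to_class,
                        stoichiometry = c("a1b2g2", "free")) {
  stoichiometry <- match.arg(stoichiometry)
  stopifnot(!is.null(names(chain_to_class)),
            all(chain_to_class %in% c("alpha", "beta", "gamma")))
  df <- data.frame(chain = names(chain_to_class),
                   class = unname(chain_to_class),
                   stringsAsFactors = FALSE)
  df$copy <- stats::ave(seq_len(nrow(df)), df$class, FUN = seq_along)
  if (stoichiometry == "a1b2g2") {
    if (nrow(df) != 5)
      stop("subunit-count error: a pentamer needs exactly 5 chains, got ",
           nrow(df))
    cnt <- table(factor(df$class, c("alpha", "beta", "gamma")))
    if (!all(cnt == c(2, 2, 1)))
      stop("alpha1-beta2-gamma2 composition requires 2 alpha, 2 beta, ",
           "1 gamma chains; got ", paste(cnt, collapse = "/"))
  }
  structure(df, stoichiometry = stoichiometry,
            class = c("SubunitMap", "data.frame"))
}

#' Default alpha1-beta2-gamma2 GABA-A receptor conventions
#'
#' The shipped configuration used throughout the package: M2 prime-position
#' anchors (the 9-prime leucine residue number per subunit class, from which
#' prime index k maps to residue `anchor + (k - 9)`), and the upper-ECD
#' residue-number intervals per class used for the ECD-spread metric.
#'
#' Anchors follow the receptor's author numbering: alpha1 L264 (so 2' is
#' V257), beta2 L259 (2' A252), gamma2 L274. Upper-ECD intervals: alpha1
#' 10-45, 66-102, 107-133, 157-180, 200-213; beta2 7-43, 62-99, 104-130,
#' 154-176, 194-208; gamma2 25-57, 77-113, 119-145, 169-189, 210-223.
#'
#' @return list with `anchors` (named integer vector) and `ecd_ranges`
#'   (named list of 2-column interval matrices, class `EcdRanges`).
#' @export
gabaa_config <- function() {
  list(
    anchors = c(alpha = 264L, beta = 259L, gamma = 274L),
    ecd_ranges = ecd_ranges(list(
      alpha = rbind(c(10, 45), c(66, 102), c(107, 133), c(157, 180), c(200, 213)),
      beta  = rbind(c(7, 43), c(62, 99), c(104, 130), c(154, 176), c(194, 208)),
      gamma = rbind(c(25, 57), c(77, 113), c(119, 145), c(169, 189), c(210, 223)))))
}

#' Upper-ECD residue ranges
#' @param ranges named list (per subunit class) of 2-column matrices of
#'   inclusive residue-number intervals.
#' @return object of class `EcdRanges`.
#' @export
ecd_ranges <- function(ranges) {
  stopifnot(is.list(ranges), !is.null(names(ranges)))
  for (cl in names(ranges)) {
    m <- ranges[[cl]]
    stopifnot(is.matrix(m), ncol(m) == 2, all(m[, 1] <= m[, 2]))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("overlapping upper-ECD intervals for class ", cl)
    ranges[[cl]] <- m
  }
  structure(ranges, class = "EcdRanges")
}

#' Build an M2 prime-numbering map
#'
#' Maps prime indices k in [-2, 20] to residue numbers per subunit class via
#' `residue = anchor + (k - 9)`, where the anchor is the 9' residue (the
#' conserved activation-gate leucine in GABA-A subunits). The anchor residue
#' of each chain is checked against the structure: a missing anchor is an
#' error; an anchor that is not leucine only warns, so engineered constructs
#' (e.g. 2'-serine mutants elsewhere, or non-Leu anchors) remain usable.
#' Residue ranges crossing insertion codes are refused because the
#' anchor+offset rule assumes contiguous author numbering.
#'
#' @param structure a `Structure`.
#' @param subunits a `SubunitMap`.
#' @param anchors named integer vector of 9' residue numbers per class
#'   (default: [gabaa_config()] anchors).
#' @param prime_range integer range of prime indices (default -2:20).
#' @return object of class `PrimeMap`: data frame (chain, class, prime,
#'   resno) with attributes `anchors` and `prime_range`.
#' @export
build_prime_map <- function(structure, subunits,
                            anchors = gabaa_config()$anchors,
                            prime_range = -2:20) {
  stopifnot(inherits(structure, "Structure"), inherits(subunits, "SubunitMap"))
  miss <- setdiff(unique(subunits$class), names(anchors))
  if (length(miss)) stop("no anchor given for class(es): ",
                         paste(miss, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(subunits))) {
    ch <- subunits$chain[i]; cl <- subunits$class[i]
    anchor <- as.integer(anchors[[cl]])
    in_chain <- structure$chain == ch
    anchor_rows <- in_chain & structure$resno == anchor
    if (!any(anchor_rows))
      stop("anchor residue ", anchor, " missing in chain ", ch)
    aa <- unique(structure$resid[anchor_rows])
    if (!any(aa %in% c("LEU")))
      warning("anchor residue ", anchor, " in chain ", ch, " is ",
              paste(aa, collapse = "/"), ", not LEU")
    resnos <- anchor + (prime_range - 9L)
    span <- in_chain & structure$resno >= min(resnos) &
      structure$resno <= max(resnos)
    if (any(nzchar(structure$insert[span])))
      stop("prime range crosses an insertion code in chain ", ch,
           "; anchor+offset numbering is not applicable")
    rows[[i]] <- data.frame(chain = ch, class = cl, prime = prime_range,
                            resno = resnos, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, anchors = anchors, prime_range = range(prime_range),
            class = c("PrimeMap", "data.frame"))
}

#' Residue numbers of one prime position
#' @param prime_map a `PrimeMap`.
#' @param prime prime index.
#' @return data frame (chain, class, resno) of the ring residues.
#' @export
prime_residues <- function(prime_map, prime) {
  stopifnot(inherits(prime_map, "PrimeMap"))
  hit <- prime_map$prime == prime
  if (!any(hit)) stop("prime index ", prime, " outside the mapped range")
  prime_map[hit, c("chain", "class", "resno")]
}

#' Atom selection for a prime-position ring
#' @param structure a `Structure`.
#' @param prime_map a `PrimeMap`.
#' @param prime prime index.
#' @param elety optional atom-name filter (e.g. `"CA"`).
#' @return `Selection` of all matching atoms of the five ring residues.
#' @export
select_prime_ring <- function(structure, prime_map, prime, elety = NULL) {
  res <- prime_residues(prime_map, prime)
  idx <- integer(0)
  for (i in seq_len(nrow(res)))
    idx <- c(idx, select_atoms(structure, chain = res$chain[i],
                               resno = res$resno[i], elety = elety))
  structure(sort(unique(idx)),
            expr = sprintf("prime %d ring%s", prime,
                           if (is.null(elety)) "" else paste0(" [", elety, "]")),
            class = "Selection")
}

#' Infer an alpha1-beta2-gamma2 subunit map from residue identities
#'
#' Scores each chain against the class-specific M2 signature of the shipped
#' numbering (9' leucine at the class anchor; 2' valine for alpha at
#' anchor-7, 2' alanine for beta) and assigns classes so that the composition
#' is 2 alpha / 2 beta / 1 gamma. Intended for deposited coordinate files
#' whose chain lettering is not known in advance.
#'
#' @param structure a `Structure`.
#' @param anchors named integer vector of 9' anchors per class.
#' @return a `SubunitMap`.
#' @export
infer_subunit_map <- function(structure, anchors = gabaa_config()$anchors) {
  chains <- sort(unique(structure$chain[structure$resid %in% .standard_aa]))
  if (length(chains) < 5)
    stop("subunit-count error: need 5 protein chains, found ", length(chains))
  resid_at <- function(ch, rn) {
    r <- unique(structure$resid[structure$chain == ch & structure$resno == rn])
    if (length(r)) r[1] else NA_character_
  }
  score <- sapply(chains, function(ch) c(
    alpha = sum(c(identical(resid_at(ch, anchors[["alpha"]]), "LEU"),
                  identical(resid_at(ch, anchors[["alpha"]] - 7L), "VAL"))),
    beta  = sum(c(identical(resid_at(ch, anchors[["beta"]]), "LEU"),
                  identical(resid_at(ch, anchors[["beta"]] - 7L), "ALA"))),
    gamma = sum(identical(resid_at(ch, anchors[["gamma"]]), "LEU"))))
  # greedy assignment honouring the 2/2/1 quota
  quota <- c(alpha = 2L, beta = 2L, gamma = 1L)
  assign <- setNames(rep(NA_character_, length(chains)), chains)
  ord <- order(-apply(score, 2, max))
  for (j in ord) {
    prefs <- names(sort(score[, j], decreasing = TRUE))
    for (p in prefs) if (quota[[p]] > 0L) {
      assign[j] <- p; quota[[p]] <- quota[[p]] - 1L; break
    }
  }
  assign <- assign[!is.na(assign)]
  if (length(assign) != 5)
    stop("could not assign an alpha1-beta2-gamma2 composition (",
         length(assign), " chains classed)")
  subunit_map(assign[order(names(assign))])
}
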