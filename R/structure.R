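# Canonical atom-table columns shared by every Structure.
.atom_cols <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "altloc", "occ", "b")

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.water_resnames <- c("HOH", "WAT", "TIP3", "SOL")

# Average atomic masses (Da) for COM weighting.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, CL = 35.45, NA. = 22.99)

#' Construct a Structure from an atom table
#'
#' A `Structure` is a data frame of atom records (one row per atom) with the
#' columns `chain`, `resno`, `insert`, `resid`, `elety`, `element`, `x`, `y`,
#' `z`, `altloc`, `occ`, `b`, carrying the coordinates of one model. Positions
#' are in Angstrom, residue numbering is the author-assigned numbering of the
#' source coordinate file (1-based), and atom indices used elsewhere in the
#' package are plain row indices into this table.
#'
#' @param atoms data frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; missing optional columns are filled with defaults
#'   (`insert`/`altloc` empty, `occ` 1, `b` 0, `element` derived from the
#'   first letter of the atom name).
#' @param model_id integer model identifier (default 1).
#' @return object of class `Structure`.
#' @export
as_structure <- function(atoms, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty model: a Structure must contain at least one atom")
  df <- data.frame(
    chain   = as.character(atoms$chain),
    resno   = as.integer(atoms$resno),
    insert  = if ("insert" %in% names(atoms)) .blank(atoms$insert) else "",
    resid   = as.character(atoms$resid),
    elety   = as.character(atoms$elety),
    element = if ("element" %in% names(atoms)) toupper(.blank(atoms$element))
              else guess_element(atoms$elety),
    x = as.numeric(atoms$x), y = as.numeric(atoms$y), z = as.numeric(atoms$z),
    altloc  = if ("altloc" %in% names(atoms)) .blank(atoms$altloc) else "",
    occ     = if ("occ" %in% names(atoms)) as.numeric(atoms$occ) else 1,
    b       = if ("b" %in% names(atoms)) as.numeric(atoms$b) else 0,
    stringsAsFactors = FALSE)
  blank_el <- !nzchar(df$element)
  if (any(blank_el)) df$element[blank_el] <- guess_element(df$elety[blank_el])
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates in atom table")
  if (any(df$occ < 0 | df$occ > 1, na.rm = TRUE))
    stop("occupancies must lie in [0, 1]")
  rownames(df) <- NULL
  structure(df, model_id = as.integer(model_id),
            class = c("Structure", "data.frame"))
}

.blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  trimws(x)
}

#' Derive an element symbol from a PDB atom name
#'
#' Strips digits/primes and takes the leading alphabetic character; recognises
#' two-letter elements commonly seen in these systems (CL, NA, MG, ZN).
#' @param elety character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(elety)))
  two <- c("CL", "NA", "MG", "ZN", "BR", "FE")
  ifelse(nm %in% two, nm, substr(nm, 1, 1))
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d chains (%s), model %d\n",
              nrow(x), length(unique(x$chain)),
              paste(sort(unique(x$chain)), collapse = ","),
              attr(x, "model_id") %||% 1L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate matrix of a Structure
#' @param s a `Structure`.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure"))
  cbind(x = s$x, y = s$y, z = s$z)
}

#' Replace the coordinates of a Structure
#' @param s a `Structure`.
#' @param xyz n x 3 matrix of new coordinates.
#' @return the modified `Structure`.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "Structure"), is.matrix(xyz),
            nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

#' Atomic masses for a Structure
#' @param s a `Structure`.
#' @return numeric vector of masses (Da); unknown elements get carbon's mass.
#' @export
atom_masses <- function(s) {
  m <- .atomic_masses[s$element]
  m[is.na(m)] <- .atomic_masses[["C"]]
  unname(m)
}

#' Select atoms of a Structure
#'
#' Resolves a simple attribute filter into a `Selection`: an integer vector of
#' row indices into the structure's atom table, carrying the expression that
#' produced it. All arguments are combined with AND; `NULL` means "no
#' constraint".
#'
#' @param s a `Structure`.
#' @param chain,resid,elety,element character vectors of admissible values.
#' @param resno integer vector of admissible residue numbers.
#' @param heavy if `TRUE`, drop hydrogens.
#' @param protein if `TRUE`, keep only standard amino-acid residues.
#' @return integer vector of class `Selection` (attributes: `expr`).
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, element = NULL, heavy = FALSE,
                         protein = FALSE) {
  stopifnot(inherits(s, "Structure"))
  keep <- rep(TRUE, nrow(s))
  if (!is.null(chain))   keep <- keep & s$chain %in% chain
  if (!is.null(resno))   keep <- keep & s$resno %in% resno
  if (!is.null(resid))   keep <- keep & s$resid %in% resid
  if (!is.null(elety))   keep <- keep & s$elety %in% elety
  if (!is.null(element)) keep <- keep & s$element %in% element
  if (heavy)             keep <- keep & s$element != "H"
  if (protein)           keep <- keep & s$resid %in% .standard_aa
  idx <- which(keep)
  expr <- paste(c(
    if (!is.null(chain)) paste0("chain %in% {", paste(chain, collapse = ","), "}"),
    if (!is.null(resno)) paste0("resno in [", min(resno), ",", max(resno), "]"),
    if (!is.null(resid)) paste0("resid %in% {", paste(resid, collapse = ","), "}"),
    if (!is.null(elety)) paste0("elety %in% {", paste(elety, collapse = ","), "}"),
    if (!is.null(element)) paste0("element %in% {", paste(element, collapse = ","), "}"),
    if (heavy) "heavy", if (protein) "protein"), collapse = " & ")
  structure(idx, expr = if (nzchar(expr)) expr else "all", class = "Selection")
}

#' Protein C-alpha selection
#' @param s a `Structure`.
#' @return `Selection` of CA atoms in standard amino-acid residues.
#' @export
select_calpha <- function(s) select_atoms(s, elety = "CA", protein = TRUE)

#' Mass-weighted centre of mass
#' @param s a `Structure`.
#' @param sel optional `Selection` (default: all atoms).
#' @param xyz optional replacement coordinate matrix (same atom order as `s`).
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return length-3 numeric vector (Angstrom).
#' @export
centre_of_mass <- function(s, sel = NULL, xyz = NULL, mass_weighted = TRUE) {
  if (is.null(xyz)) xyz <- coords(s)
  if (!is.null(sel)) {
    xyz <- xyz[sel, , drop = FALSE]
    m <- if (mass_weighted) atom_masses(s)[sel] else rep(1, length(sel))
  } else {
    m <- if (mass_weighted) atom_masses(s) else rep(1, nrow(xyz))
  }
  colSums(xyz * m) / sum(m)
}
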