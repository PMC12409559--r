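## PDB reading/writing, header metadata, atom classification.
## Atom records are kept in a plain data.frame (bio3d style); a
## structure_model wraps the table together with per-crystal metadata.

# Standard amino-acid 3-letter codes (plus selenomethionine).
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")

# Common monoatomic ion residue names seen in HETATM records.
.ION_RES <- c("CA", "ZN", "MG", "NA", "K", "CL", "MN", "FE", "CU", "NI",
              "CO", "CD", "BR", "IOD", "SR", "CS")

.WATER_RES <- c("HOH", "WAT")

#' Classify atoms into analysis selections
#'
#' Deterministically assigns each atom to one of the selections used
#' throughout the package: `calpha`, `backbone`, `side_chain`, `water`,
#' `ion`, `ligand` or `hydrogen`. Amino-acid N/C/O/OXT are backbone and
#' CA is calpha; every other amino-acid heavy atom is side chain
#' (glycine therefore contributes none). Waters are identified by
#' residue name HOH/WAT only; known monoatomic ion residues map to
#' `ion`; any other het group maps to `ligand`. Hydrogens (and
#' deuteriums) are always `hydrogen` and are excluded from downstream
#' selections.
#'
#' @param residue_name character vector of 3-letter residue codes.
#' @param atom_name character vector of PDB atom names.
#' @param element character vector of element symbols.
#' @return character vector of atom classes, same length as the inputs.
#' @export
classify_atoms <- function(residue_name, atom_name, element) {
  residue_name <- toupper(trimws(residue_name))
  atom_name <- toupper(trimws(atom_name))
  element <- toupper(trimws(element))
  if (any(!nzchar(residue_name)) || any(!nzchar(atom_name)))
    stop("residue and atom names must be non-empty")
  n <- length(residue_name)
  cls <- rep("ligand", n)
  hyd <- element %in% c("H", "D")
  aa <- residue_name %in% .AA3
  cls[aa & atom_name %in% c("N", "C", "O", "OXT")] <- "backbone"
  cls[aa & atom_name == "CA"] <- "calpha"
  cls[aa & !atom_name %in% c("N", "CA", "C", "O", "OXT")] <- "side_chain"
  cls[residue_name %in% .WATER_RES] <- "water"
  cls[!aa & residue_name %in% .ION_RES] <- "ion"
  cls[hyd] <- "hydrogen"
  cls
}

#' Construct a structure model
#'
#' @param structure_id identifier string (e.g. a PDB ID).
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `element`, `x`, `y`, `z`,
#'   `occ`, `b`, `atom_class`.
#' @param temperature_K data-collection temperature in Kelvin, or `NULL`.
#' @param wilson_b Wilson-plot average B in square Angstrom, or `NULL`.
#' @param replicate_id integer replicate index, or `NULL`.
#' @param cell unit-cell parameters `c(a, b, c, alpha, beta, gamma)`, or `NULL`.
#' @param r_work,r_free refinement R values when known.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(structure_id, atoms, temperature_K = NULL,
                            wilson_b = NULL, replicate_id = NULL,
                            cell = NULL, r_work = NULL, r_free = NULL) {
  need <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "element", "x", "y", "z", "occ", "b", "atom_class")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (any(atoms$b < 0)) stop("negative B-factor in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0, 1]")
  if (!is.null(temperature_K) && (!is.finite(temperature_K) || temperature_K <= 0))
    stop("temperature_K must be positive when present")
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms,
                 temperature_K = temperature_K, wilson_b = wilson_b,
                 replicate_id = replicate_id, cell = cell,
                 r_work = r_work, r_free = r_free),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model ", x$structure_id, ": ", nrow(x$atoms), " atoms",
      if (!is.null(x$temperature_K)) sprintf(", T = %g K", x$temperature_K),
      if (!is.null(x$wilson_b)) sprintf(", Wilson B = %g A^2", x$wilson_b),
      "\n", sep = "")
  print(table(x$atoms$atom_class))
  invisible(x)
}

# residue key used everywhere for matching (author numbering + icode)
.res_key <- function(atoms) paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
.atom_key <- function(atoms) paste(.res_key(atoms), atoms$name, sep = "|")

# first numeric value after ':' on lines matching pattern
.header_number <- function(lines, pattern) {
  hits <- grep(pattern, lines, value = TRUE)
  for (h in hits) {
    v <- suppressWarnings(as.numeric(trimws(sub("^[^:]*:", "", h))))
    if (length(v) == 1 && is.finite(v)) return(v)
  }
  NULL
}

.parse_cryst1 <- function(lines) {
  h <- grep("^CRYST1", lines, value = TRUE)
  if (!length(h)) return(NULL)
  h <- h[1]
  f <- function(a, b) suppressWarnings(as.numeric(substr(h, a, b)))
  cell <- c(f(7, 15), f(16, 24), f(25, 33), f(34, 40), f(41, 47), f(48, 54))
  if (any(!is.finite(cell))) return(NULL)
  names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  cell
}

# Resolve alternate locations: one record per (chain, resseq, icode, name).
.resolve_altlocs <- function(atoms, policy) {
  key <- .atom_key(atoms)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    if (policy == "first") return(idx[1])
    occ <- atoms$occ[idx]
    cand <- idx[occ == max(occ)]
    # tie on occupancy: lexicographically smallest altloc id
    cand[order(atoms$altloc[cand])][1]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (fixed-column semantics via bio3d),
#' resolves alternate locations to a single record per atom, classifies
#' atoms into analysis selections, and extracts the data-collection
#' temperature (REMARK 200), Wilson B (REMARK 3), R values and CRYST1
#' cell when present. Only the first MODEL of a multi-model file is
#' read (with a warning). Hydrogens are retained but classified as
#' `hydrogen`.
#'
#' @param path path to a PDB-format text file.
#' @param altloc_policy `"highest_occupancy"` (ties broken by smallest
#'   altloc identifier) or `"first"` (file order).
#' @param structure_id identifier for the model; defaults to the file
#'   base name.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, altloc_policy = c("highest_occupancy", "first"),
                           structure_id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  src <- path
  if (sum(grepl("^MODEL ", lines)) > 1) {
    warning("multi-model file: only the first MODEL is read (", path, ")")
    endm <- grep("^ENDMDL", lines)[1]
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines[seq_len(endm)], src)
  }
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(src, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = toupper(trimws(blank(a$elety))),
    altloc = toupper(trimws(blank(a$alt))),
    resname = toupper(trimws(blank(a$resid))),
    chain = blank(a$chain),
    resseq = as.integer(a$resno),
    icode = trimws(blank(a$insert)),
    element = toupper(trimws(blank(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  # element fallback from atom name when the element column is blank
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- substr(gsub("[^A-Z]", "", atoms$name[noel]), 1, 1)
  atoms <- .resolve_altlocs(atoms, altloc_policy)
  atoms$atom_class <- classify_atoms(atoms$resname, atoms$name, atoms$element)
  structure_model(
    structure_id = if (is.null(structure_id))
      sub("\\.[^.]*$", "", basename(path)) else structure_id,
    atoms = atoms,
    temperature_K = .header_number(lines, "^REMARK 200.*TEMPERATURE.*\\(KELVIN\\)"),
    wilson_b = .header_number(lines, "^REMARK   3.*WILSON PLOT.*\\(A\\*\\*2\\)"),
    cell = .parse_cryst1(lines),
    r_work = .header_number(lines, "^REMARK   3   R VALUE.*\\(WORKING SET\\)"),
    r_free = .header_number(lines, "^REMARK   3   FREE R VALUE +:"))
}

#' Write a structure to a PDB-format file
#'
#' Emits REMARK 200 (temperature), REMARK 3 (Wilson B) and CRYST1 lines
#' when the corresponding metadata are present, followed by fixed-width
#' ATOM/HETATM records (waters, ions and ligands as HETATM).
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  atoms <- model$atoms
  if (!nrow(atoms)) stop("refusing to write an empty structure")
  if (any(abs(atoms[, c("x", "y", "z")]) >= 1e4))
    stop("coordinate overflow: PDB fields hold |coord| < 10^4 Angstrom")
  if (any(atoms$b >= 1e3))
    stop("B-factor overflow: PDB fields hold B < 10^3 A^2")
  hdr <- character()
  if (!is.null(model$temperature_K))
    hdr <- c(hdr, sprintf("REMARK 200  TEMPERATURE           (KELVIN) : %g",
                          model$temperature_K))
  if (!is.null(model$wilson_b))
    hdr <- c(hdr, sprintf("REMARK   3   FROM WILSON PLOT           (A**2) : %.2f",
                          model$wilson_b))
  if (!is.null(model$cell))
    hdr <- c(hdr, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                          model$cell[1], model$cell[2], model$cell[3],
                          model$cell[4], model$cell[5], model$cell[6]))
  writeLines(hdr, path)
  het <- atoms$atom_class %in% c("water", "ion", "ligand")
  bio3d::write.pdb(
    file = path, append = TRUE,
    xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = atoms$resseq, resid = atoms$resname,
    eleno = atoms$serial, elety = atoms$name,
    chain = atoms$chain, insert = ifelse(nzchar(atoms$icode), atoms$icode, ""),
    alt = ifelse(nzchar(atoms$altloc), atoms$altloc, ""),
    o = atoms$occ, b = atoms$b, elesy = atoms$element)
  invisible(path)
}

#' Resolve the data-collection temperature of a structure
#'
#' An explicit override table takes precedence over the REMARK 200
#' header value (deposited headers occasionally disagree with the
#' experiment log).
#'
#' @param model a [structure_model()].
#' @param override_table named numeric vector/list mapping structure_id
#'   to Kelvin; may be empty or `NULL`.
#' @return temperature in Kelvin.
#' @export
resolve_temperature <- function(model, override_table = NULL) {
  id <- model$structure_id
  if (!is.null(override_table) && id %in% names(override_table)) {
    t <- as.numeric(override_table[[id]])
    if (!is.finite(t) || t <= 0) stop("invalid override temperature for ", id)
    return(t)
  }
  if (!is.null(model$temperature_K)) return(model$temperature_K)
  stop("no data-collection temperature available for structure ", id)
}

#' Construct a temperature series
#'
#' @param models list of [structure_model()] objects.
#' @param reference_id structure_id of the reference; must be a member.
#' @param require_temperature check that every model carries a
#'   temperature (needed by the fitting operations).
#' @return an object of class `temperature_series`.
#' @export
temperature_series <- function(models, reference_id, require_temperature = TRUE) {
  ids <- vapply(models, function(m) m$structure_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure_id in series")
  names(models) <- ids
  if (!reference_id %in% ids)
    stop("reference_id ", reference_id, " is not in the series")
  if (require_temperature) {
    none <- ids[vapply(models, function(m) is.null(m$temperature_K), logical(1))]
    if (length(none))
      stop("models without temperature_K: ", paste(none, collapse = ", "))
  }
  structure(list(models = models, reference_id = reference_id),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  tt <- vapply(x$models, function(m)
    if (is.null(m$temperature_K)) NA_real_ else m$temperature_K, numeric(1))
  cat("temperature_series: ", length(x$models), " structures, reference ",
      x$reference_id, "\n", sep = "")
  if (any(is.finite(tt)))
    cat("temperatures (K): ", paste(sort(unique(tt[is.finite(tt)])), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

.series_temperatures <- function(series) {
  vapply(series$models, function(m) resolve_temperature(m), numeric(1))
}

#' Read a temperature series from a manifest
#'
#' The manifest is a TSV with columns `structure_id`, `path`,
#' `temperature_K` and `replicate_id`. Relative paths are resolved
#' against the manifest's directory. A temperature given in the
#' manifest overrides the file's REMARK 200 value.
#'
#' @param manifest path to the manifest TSV.
#' @param reference_id reference structure; defaults to the first row.
#' @param altloc_policy passed to [read_structure()].
#' @param override_table optional named temperature overrides, applied
#'   after the manifest column.
#' @return a [temperature_series()].
#' @export
read_series <- function(manifest, reference_id = NULL,
                        altloc_policy = "highest_occupancy",
                        override_table = NULL) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("structure_id", "path", "temperature_K", "replicate_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest ", manifest, " lacks columns: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(manifest))
  models <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, tab$path[i])
    if (!file.exists(p))
      stop("manifest ", manifest, " line ", i + 1, ": file not found: ", tab$path[i])
    m <- read_structure(p, altloc_policy = altloc_policy,
                        structure_id = tab$structure_id[i])
    if (is.finite(tab$temperature_K[i])) m$temperature_K <- tab$temperature_K[i]
    m$temperature_K <- resolve_temperature(m, override_table)
    m$replicate_id <- tab$replicate_id[i]
    m
  })
  if (is.null(reference_id)) reference_id <- tab$structure_id[1]
  temperature_series(models, reference_id)
}
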