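# Van der Waals radii (A) by element, after Bondi; used for SASA.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)
DEFAULT_RADIUS <- 1.80

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            UNK = "X")
AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

element_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_RADIUS
  unname(r)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(at) == 0L) stop("no ATOM records in ", path)
  f <- function(a, b) trimws(substr(at, a, b))
  elem <- f(77, 78)
  name <- f(13, 16)
  # infer element from atom name when column 77-78 is blank
  guess <- sub("^[0-9]*", "", name)
  elem <- ifelse(nzchar(elem), elem, substr(guess, 1, 1))
  data.frame(atom = name, resname = f(18, 20), chain = f(22, 22),
             resno = as.integer(f(23, 26)),
             x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)),
             z = as.numeric(f(47, 54)),
             b = suppressWarnings(as.numeric(f(61, 66))),
             element = toupper(elem), stringsAsFactors = FALSE)
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines)
  if (length(hdr) == 0L) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  body_start <- max(hdr) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  tok <- strsplit(body, "[[:space:]]+")
  if (any(lengths(tok) != length(fields)))
    stop("malformed _atom_site loop in ", path)
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  need <- function(nm, alt = NULL) {
    if (nm %in% fields) return(m[, nm])
    if (!is.null(alt) && alt %in% fields) return(m[, alt])
    stop("mmCIF missing _atom_site.", nm)
  }
  data.frame(
    atom = need("label_atom_id", "auth_atom_id"),
    resname = need("label_comp_id", "auth_comp_id"),
    chain = need("auth_asym_id", "label_asym_id"),
    resno = as.integer(need("auth_seq_id", "label_seq_id")),
    x = as.numeric(need("Cartn_x")), y = as.numeric(need("Cartn_y")),
    z = as.numeric(need("Cartn_z")),
    b = suppressWarnings(as.numeric(
      if ("B_iso_or_equiv" %in% fields) m[, "B_iso_or_equiv"] else NA)),
    element = toupper(need("type_symbol", "label_atom_id")),
    stringsAsFactors = FALSE)
}

atoms_to_chain <- function(atoms, chain_id) {
  a <- atoms[atoms$chain == chain_id, , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  resnos <- unique(a$resno)
  ca <- a[a$atom == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (!all(resnos %in% ca$resno))
    stop("chain ", chain_id, ": residues without CA atoms")
  seq1 <- AA3TO1[ca$resname]
  seq1[is.na(seq1)] <- "X"
  a$radius <- element_radius(a$element)
  structure(
    list(chain_id = chain_id,
         sequence = paste(seq1, collapse = ""),
         resno = ca$resno,
         ca = unname(as.matrix(ca[, c("x", "y", "z")])),
         plddt = ifelse(is.na(ca$b), 0, ca$b),
         atoms = a),
    class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s: %d residues, %d atoms\n", x$chain_id,
              nchar(x$sequence), nrow(x$atoms)))
  invisible(x)
}

#' Load a predicted two-chain model with its PAE and score metadata
#'
#' Reads coordinates (PDB or mmCIF, decided by extension), the predicted
#' aligned error matrix (JSON: either a bare LxL array or an object with a
#' `pae` / `predicted_aligned_error` field) and the ranking metadata (flat
#' JSON with `iptm`, `ptm`, optional `disorder_frac` and `version`,
#' `"AF2-like"` or `"AF3-like"`). PAE rows/columns are ordered chain A
#' residues first, then chain B; residue indexing is 1-based per chain.
#'
#' @param coords path to a PDB (`.pdb`) or mmCIF (`.cif`/`.mmcif`) file
#'   containing exactly two chains with Calpha atoms.
#' @param pae path to the PAE JSON.
#' @param scores path to the score JSON.
#' @return a `dimer_model`: list with `bait` and `prey` ([chain_model]s, in
#'   chain-id order), `pae` (LxL matrix), and `score` (a `model_score`).
#' @export
load_dimer_model <- function(coords, pae, scores) {
  ext <- tolower(tools::file_ext(coords))
  atoms <- switch(ext,
                  pdb = parse_pdb_atoms(coords),
                  cif = ,
                  mmcif = parse_mmcif_atoms(coords),
                  stop("unknown coordinate format: .", ext,
                       " (expected .pdb or .cif)"))
  chains <- sort(unique(atoms$chain))
  if (length(chains) != 2L)
    stop("expected exactly 2 chains, found ", length(chains), ": ",
         paste(chains, collapse = ", "))
  bait <- atoms_to_chain(atoms, chains[1])
  prey <- atoms_to_chain(atoms, chains[2])
  L <- nchar(bait$sequence) + nchar(prey$sequence)
  p <- jsonlite::read_json(pae, simplifyVector = TRUE)
  if (is.list(p) && !is.null(p$predicted_aligned_error))
    p <- p$predicted_aligned_error
  else if (is.list(p) && !is.null(p$pae)) p <- p$pae
  p <- as.matrix(p)
  if (nrow(p) != L || ncol(p) != L)
    stop("PAE dimension ", nrow(p), "x", ncol(p),
         " does not match total residue count ", L)
  if (any(p < 0)) stop("negative PAE values")
  sc <- jsonlite::read_json(scores, simplifyVector = TRUE)
  score <- model_score(iptm = sc$iptm, ptm = sc$ptm,
                       disorder_frac = sc$disorder_frac,
                       version = if (is.null(sc$version)) "AF2-like"
                                 else sc$version)
  structure(list(bait = bait, prey = prey, pae = unname(p), score = score),
            class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat(sprintf("<dimer_model> %s (%d aa) / %s (%d aa), ranking %.3f\n",
              x$bait$chain_id, nchar(x$bait$sequence),
              x$prey$chain_id, nchar(x$prey$sequence),
              ranking_score(x$score)))
  invisible(x)
}

#' Model score metadata
#'
#' @param iptm interface predicted TM-score in \[0,1\].
#' @param ptm predicted TM-score in \[0,1\].
#' @param disorder_frac fraction of disordered residues (required for
#'   AF3-like scores, ignored otherwise).
#' @param version `"AF2-like"` or `"AF3-like"`.
#' @return a `model_score` object.
#' @export
model_score <- function(iptm, ptm, disorder_frac = NULL,
                        version = c("AF2-like", "AF3-like")) {
  version <- match.arg(version)
  stopifnot(iptm >= 0, iptm <= 1, ptm >= 0, ptm <= 1)
  if (version == "AF3-like" &&
      (is.null(disorder_frac) || is.na(disorder_frac)))
    stop("AF3-like scores require disorder_frac")
  structure(list(iptm = iptm, ptm = ptm,
                 disorder_frac = if (is.null(disorder_frac)) NA_real_
                                 else disorder_frac,
                 version = version),
            class = "model_score")
}

#' Ranking score of a predicted model
#'
#' `0.8 iptm + 0.2 ptm` for AF2-like models;
#' `0.8 iptm + 0.2 ptm + 0.5 disorder_frac` for AF3-like models. The value
#' is reported as the formula yields it, without clamping.
#'
#' @param s a [model_score()].
#' @return the ranking score.
#' @export
ranking_score <- function(s) {
  stopifnot(inherits(s, "model_score"))
  base <- 0.8 * s$iptm + 0.2 * s$ptm
  if (s$version == "AF3-like") base + 0.5 * s$disorder_frac else base
}

write_pdb <- function(chains, path) {
  # chains: list of chain_model-like lists with $atoms data frames
  out <- character(0)
  serial <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, a$resname[i], a$chain[i], a$resno[i],
        a$x[i], a$y[i], a$z[i], 1.0,
        if (is.na(a$b[i])) 0 else a$b[i], a$element[i]))
    }
    out <- c(out, "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
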