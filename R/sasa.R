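fibonacci_sphere <- function(n) {
  # deterministic quasi-uniform unit sphere points (golden-angle spiral)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley quadrature
#'
#' Places `n_points` quasi-uniform test points on each atom's expanded
#' sphere (van der Waals radius + probe) and counts the points not buried
#' inside any neighboring expanded sphere; the accessible fraction times
#' the sphere area gives the per-atom SASA.
#'
#' @param coords n x 3 matrix of atom centers (Angstrom).
#' @param radii length-n van der Waals radii.
#' @param probe_radius solvent probe radius (default 1.4 A, water).
#' @param n_points quadrature points per atom (default 960).
#' @return list with `total` (A^2) and `per_atom`.
#' @export
shrake_rupley <- function(coords, radii, probe_radius = 1.4,
                          n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) return(list(total = 0, per_atom = numeric(0)))
  stopifnot(length(radii) == n, all(is.finite(coords)))
  sph <- fibonacci_sphere(n_points)
  R <- radii + probe_radius
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sph * R[i], 2, coords[i, ], "+")
    # neighbors whose expanded spheres can reach atom i's surface
    d2ij <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2ij < (R + R[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- colSums((t(pts) - coords[j, ])^2)
      acc <- acc & d2 >= R[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- mean(acc) * 4 * pi * R[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

residue_atoms <- function(chain, residues) {
  a <- chain$atoms[chain$atoms$resno %in% chain$resno[residues], ,
                   drop = FALSE]
  if (length(residues) && nrow(a) == 0L)
    stop("no atoms for constrained residues ",
         paste(head(residues, 5), collapse = ","), " of chain ",
         chain$chain_id)
  missing <- setdiff(chain$resno[residues], a$resno)
  if (length(missing))
    stop("missing atoms for residue(s) ", paste(missing, collapse = ","),
         " of chain ", chain$chain_id)
  a
}

#' Buried interface area over the mutually constrained residues
#'
#' Isolates the constrained residues of each chain and computes the buried
#' solvent-accessible area of the two selections,
#' `0.5 * (SASA(A alone) + SASA(B alone) - SASA(A u B in complex))`,
#' then normalizes by the product of the two full chain lengths to give a
#' size-independent interface score.
#'
#' @param model a `dimer_model` whose atom records cover the constrained
#'   residues.
#' @param pairs optional precomputed [constrained_pairs()]; computed with
#'   default thresholds when missing.
#' @param probe_radius solvent probe radius (default 1.4 A).
#' @param n_points Shrake-Rupley quadrature points (default 960).
#' @return list with `buried_area` (A^2) and `area_norm`
#'   (`buried_area / (len_bait * len_prey)`); both 0 for an empty
#'   constrained set.
#' @export
interface_area <- function(model, pairs = NULL, probe_radius = 1.4,
                           n_points = 960) {
  if (is.null(pairs)) pairs <- constrained_pairs(model)
  if (nrow(pairs) == 0L) return(list(buried_area = 0, area_norm = 0))
  aa <- residue_atoms(model$bait, unique(pairs$res_bait))
  ab <- residue_atoms(model$prey, unique(pairs$res_prey))
  xa <- as.matrix(aa[, c("x", "y", "z")]); ra <- aa$radius
  xb <- as.matrix(ab[, c("x", "y", "z")]); rb <- ab$radius
  sa <- shrake_rupley(xa, ra, probe_radius, n_points)$total
  sb <- shrake_rupley(xb, rb, probe_radius, n_points)$total
  sab <- shrake_rupley(rbind(xa, xb), c(ra, rb), probe_radius,
                       n_points)$total
  buried <- max(0.5 * (sa + sb - sab), 0)
  list(buried_area = buried,
       area_norm = buried /
         (nchar(model$bait$sequence) * nchar(model$prey$sequence)))
}
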