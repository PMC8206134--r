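#' Atomic coordinate model
#'
#' A light-weight coordinate table: one row per atom with columns
#' `chain`, `resno`, `resname`, `atom`, `altloc`, `occ`, `x`, `y`, `z`
#' (Angstrom). [read_atom_model()] builds one from a PDB/mmCIF file via
#' bio3d; [atom_model()] from a data.frame (synthetic test models).
#'
#' @param df Data frame with at least `resno`, `atom`, `x`, `y`, `z`.
#' @return An object of class `atom_model`.
#' @export
atom_model <- function(df) {
  need <- c("resno", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("atom model needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$resname)) df$resname <- "ALA"
  if (is.null(df$altloc)) df$altloc <- ""
  if (is.null(df$occ)) df$occ <- 1
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates in atom model")
  structure(df[, c("chain", "resno", "resname", "atom", "altloc", "occ",
                   "x", "y", "z")],
            class = c("atom_model", "data.frame"))
}

#' @rdname atom_model
#' @param path PDB or mmCIF file path.
#' @export
read_atom_model <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_atom_model requires the bio3d package")
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  atom_model(data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                        atom = a$elety,
                        altloc = ifelse(is.na(a$alt), "", a$alt),
                        occ = a$o, x = a$x, y = a$y, z = a$z))
}

## Coordinates of one atom, preferring blank/"A" altlocs.
get_atom <- function(model, chain, resno, atom = "CA") {
  sel <- model$resno == resno & model$atom == atom &
    (is.na(model$chain) | model$chain == chain)
  rows <- model[sel, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("residue %d (atom %s, chain %s) not found", resno, atom, chain))
  rows <- rows[order(!(rows$altloc %in% c("", "A"))), , drop = FALSE]
  as.numeric(rows[1, c("x", "y", "z")])
}

#' C-alpha distance between two residues
#'
#' Euclidean distance between the Calpha atoms of two residues, the
#' nucleotide-binding-pocket descriptors: K488-R604 probes the
#' switch-1-to-P-loop gap and R406-T647 the KH0-to-switch-2 gap.
#'
#' @param model An [atom_model()].
#' @param chain Chain id.
#' @param res_a,res_b Residue numbers.
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(model, chain, res_a, res_b) {
  a <- get_atom(model, chain, res_a, "CA")
  b <- get_atom(model, chain, res_b, "CA")
  sqrt(sum((a - b)^2))
}

#' Central beta-sheet twist angle
#'
#' Angle between the vectors Calpha(475) -> Calpha(480) (beta-strand
#' KS3) and Calpha(527) -> Calpha(531) (KS4), in degrees within
#' \[0, 180\]. A less-twisted sheet (smaller angle) marks the closed
#' motor-domain conformation.
#'
#' @param model An [atom_model()].
#' @param chain Chain id.
#' @param residues The four residue numbers (KS3 pair then KS4 pair).
#' @return Angle in degrees.
#' @export
beta_sheet_twist <- function(model, chain, residues = c(475L, 480L, 527L, 531L)) {
  p <- lapply(residues, function(r) get_atom(model, chain, r, "CA"))
  v1 <- p[[2]] - p[[1]]
  v2 <- p[[4]] - p[[3]]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Conformation descriptors for one motor-domain chain
#'
#' @param model An [atom_model()].
#' @param chain Chain id.
#' @return Data frame with `d_sw1_pl` (Calpha 488-604), `d_kh0_sw2`
#'   (Calpha 406-647), `beta_twist` and the geometric `label`.
#' @export
conformation_descriptors <- function(model, chain = "A") {
  d1 <- ca_distance(model, chain, 488L, 604L)
  d2 <- ca_distance(model, chain, 406L, 647L)
  bt <- beta_sheet_twist(model, chain)
  data.frame(chain = chain, d_sw1_pl = d1, d_kh0_sw2 = d2, beta_twist = bt,
             label = classify_conformation(data.frame(d_sw1_pl = d1,
                                                      d_kh0_sw2 = d2,
                                                      beta_twist = bt)))
}

#' Classify a motor-domain conformation from its descriptors
#'
#' Rule derived from the midpoints between the descriptor group means:
#' `closed` when the KH0-to-switch-2 distance is under 17 A (closed
#' group mean 11.7 vs open-like 22.9-24.0); otherwise `semi_closed`
#' when the switch-1-to-P-loop distance is under 14 A (semi-closed 13.4
#' vs open-like >= 14.0); otherwise `open_like`. The `open*` sub-state
#' is geometrically indistinguishable from `open` and is only ever
#' assigned from metadata (nucleotide present with an undocked
#' neck-linker), never from coordinates.
#'
#' @param desc Data frame (or single-row list) with `d_sw1_pl` and
#'   `d_kh0_sw2` (Angstrom); `beta_twist` is carried but not used by
#'   the rule.
#' @param nucleotide Optional nucleotide metadata (e.g. "AMP-PNP");
#'   used with `neck_linker` to refine `open_like` into `"open_star"`.
#' @param neck_linker Optional neck-linker state string.
#' @return Character vector of labels: `"closed"`, `"semi_closed"`,
#'   `"open_like"` (or `"open_star"` when metadata warrants).
#' @export
classify_conformation <- function(desc, nucleotide = NULL, neck_linker = NULL) {
  lab <- ifelse(desc$d_kh0_sw2 < 17.0, "closed",
                ifelse(desc$d_sw1_pl < 14.0, "semi_closed", "open_like"))
  if (!is.null(nucleotide) && !is.null(neck_linker)) {
    atp_state <- nucleotide %in% c("AMP-PNP", "ADP-AlFx")
    undocked <- !grepl("^Docked", neck_linker)
    lab <- ifelse(lab == "open_like" & atp_state & undocked, "open_star", lab)
  }
  lab
}

#' Published motor-domain descriptor table
#'
#' The printed descriptor triples (two nucleotide-binding-pocket
#' Calpha distances and the central beta-sheet twist) for the 24
#' microtubule-bound KIF14 structures plus the unbound crystal
#' structure, with their conformation groups.
#'
#' @return Data frame with columns `group`, `nucleotide`, `mt_bound`,
#'   `d_sw1_pl`, `d_kh0_sw2`, `beta_twist`, `neck_linker`, `model`,
#'   `pdb_id`.
#' @export
kif14_reference_descriptors <- function() {
  utils::read.csv(system.file("extdata", "kif14_descriptors.csv",
                              package = "hasrc"), stringsAsFactors = FALSE)
}

## map Angstrom coordinates (box-centre origin) to 0-based voxel coords
coords_to_voxel <- function(map, xyz) {
  n <- dim(map$data)[1]
  xyz / map$apix + n %/% 2L
}

#' Mean map density at selected atoms
#'
#' Trilinear interpolation of the map at the atom coordinates, averaged.
#' Atoms falling outside the map are excluded and counted.
#'
#' @param map A [volume_grid()] (model and map in the same frame,
#'   box-centre origin).
#' @param model An [atom_model()].
#' @param selection Logical or integer row selection (default: all).
#' @return Mean density; attribute `"n_outside"` counts excluded atoms.
#' @export
map_mean_density <- function(map, model, selection = NULL) {
  rows <- if (is.null(selection)) model else model[selection, , drop = FALSE]
  if (!nrow(rows)) stop("empty atom selection")
  pts <- coords_to_voxel(map, as.matrix(rows[, c("x", "y", "z")]))
  v <- cpp_trilinear_sample(as.numeric(map$data), dim(map$data)[1], pts)
  out <- mean(v, na.rm = TRUE)
  attr(out, "n_outside") <- sum(is.na(v))
  out
}

#' Background density near (but off) a model
#'
#' Mean map value at probe points drawn in a spherical shell (default
#' 6-10 A) around randomly chosen selection atoms, rejecting probes
#' closer than `exclusion` (default 3.5 A) to any model atom.
#'
#' @param map A [volume_grid()].
#' @param model An [atom_model()] (the full model for exclusion).
#' @param selection Row selection defining the neighbourhood (default:
#'   all atoms).
#' @param n_probes Number of accepted probes requested.
#' @param seed Integer seed (deterministic).
#' @param shell Two-element inner/outer shell radii, Angstrom.
#' @param exclusion Minimum distance from any model atom, Angstrom.
#' @return Mean background density; attribute `"n_probes"` gives the
#'   number of accepted probes.
#' @export
background_density <- function(map, model, selection = NULL, n_probes = 400L,
                               seed = 1, shell = c(6, 10), exclusion = 3.5) {
  rows <- if (is.null(selection)) model else model[selection, , drop = FALSE]
  all_xyz <- as.matrix(model[, c("x", "y", "z")])
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(pts) < n_probes && tries < 50L) {
    tries <- tries + 1L
    m <- 4L * n_probes
    anchor <- all_xyz[sample(which(if (is.null(selection)) rep(TRUE, nrow(model))
                                   else selection_to_logical(selection, nrow(model))),
                             m, replace = TRUE), , drop = FALSE]
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(m, shell[1], shell[2])
    cand <- anchor + u * r
    ## reject probes near any model atom
    keep <- vapply(seq_len(m), function(i) {
      d2 <- (all_xyz[, 1] - cand[i, 1])^2 + (all_xyz[, 2] - cand[i, 2])^2 +
        (all_xyz[, 3] - cand[i, 3])^2
      min(d2) >= exclusion^2
    }, logical(1))
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  if (!nrow(pts)) stop("no valid background probe points found")
  pts <- pts[seq_len(min(nrow(pts), n_probes)), , drop = FALSE]
  v <- cpp_trilinear_sample(as.numeric(map$data), dim(map$data)[1],
                            coords_to_voxel(map, pts))
  out <- mean(v, na.rm = TRUE)
  attr(out, "n_probes") <- sum(!is.na(v))
  out
}

selection_to_logical <- function(selection, n) {
  if (is.logical(selection)) selection else seq_len(n) %in% selection
}

## default regions where the open and closed conformers do not overlap
## (KH0, KH1, KH2 and KH3 helices)
kh_region_residues <- function() {
  c(403:412, 463:471, 501:515, 577:579)
}

backbone_atoms <- c("N", "CA", "C", "O")

#' Open/closed relative density of a map
#'
#' Background-subtracted mean backbone density over the non-overlapping
#' open- and closed-conformation regions (KH0/KH1/KH2/KH3, residues
#' 403-412, 463-471, 501-515, 577-579) of the two aligned reference
#' models; the open fraction is `D_open / (D_open + D_closed)`.
#' Background is subtracted in both the numerator and the denominator.
#'
#' @param map A [volume_grid()].
#' @param open_model,closed_model [atom_model()]s aligned to the map.
#' @param residues Residue numbers of the region (default the KH
#'   regions above).
#' @param seed Seed for the background probes.
#' @return List with `f_open`, `f_closed`, `d_open`, `d_closed` (the
#'   background-subtracted means).
#' @export
open_closed_fraction <- function(map, open_model, closed_model,
                                 residues = kh_region_residues(), seed = 1) {
  region <- function(model) {
    sel <- model$resno %in% residues & model$atom %in% backbone_atoms
    d <- map_mean_density(map, model, sel)
    b <- background_density(map, model, sel, seed = seed)
    as.numeric(d) - as.numeric(b)
  }
  d_open <- region(open_model)
  d_closed <- region(closed_model)
  tot <- d_open + d_closed
  if (!is.finite(tot) || tot <= 0)
    stop("total open+closed density is not positive; fractions undefined")
  list(f_open = d_open / tot, f_closed = d_closed / tot,
       d_open = d_open, d_closed = d_closed)
}

## purine base atom names (ADP / AMP-PNP base moiety)
nucleotide_base_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7",
                           "C8", "N9")

#' Nucleotide relative density
#'
#' Mean density at the nucleotide base atoms divided by the mean
#' density at the P-loop residues (476-494) of the same map; the ratio
#' is invariant under global map scaling.
#'
#' @param map A [volume_grid()].
#' @param model An [atom_model()] containing the ligand (resname ADP or
#'   ANP) and the P-loop residues.
#' @param ligand_resnames Residue names treated as the nucleotide.
#' @param ploop_residues P-loop residue numbers.
#' @return The density ratio.
#' @export
nucleotide_relative_density <- function(map, model,
                                        ligand_resnames = c("ADP", "ANP", "AMP-PNP"),
                                        ploop_residues = 476:494) {
  lig <- model$resname %in% ligand_resnames
  if (!any(lig)) stop("no nucleotide ligand found in the model")
  base <- lig & model$atom %in% nucleotide_base_atoms
  if (!any(base)) base <- lig
  pl <- model$resno %in% ploop_residues & !lig
  if (!any(pl)) stop("P-loop residues missing from the model")
  num <- as.numeric(map_mean_density(map, model, base))
  den <- as.numeric(map_mean_density(map, model, pl))
  num / den
}
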