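# Methyl geometry: coordinate parsing, ILVM methyl enumeration, distances,
# chi2 dihedrals and rotamer classes.

# methyl definitions: which carbon carries each ILVM methyl, its proton
# names, pseudo-atom name and stereo descriptor
.methyl_def <- data.frame(
  restype = c("ILE", "ILE", "LEU", "LEU", "VAL", "VAL", "MET"),
  label   = c("delta1", "gamma2", "delta1", "delta2", "gamma1", "gamma2",
              "epsilon"),
  carbon  = c("CD1", "CG2", "CD1", "CD2", "CG1", "CG2", "CE"),
  pseudo  = c("QD1", "QG2", "QD1", "QD2", "QG1", "QG2", "QE"),
  prev    = c("CG1", "CB", "CG", "CG", "CB", "CB", "SD"),
  stereo  = c(NA, NA, "pro-R", "pro-S", "pro-R", "pro-S", NA),
  stringsAsFactors = FALSE)

.one_letter <- c(ILE = "I", LEU = "L", VAL = "V", MET = "M", ALA = "A",
                 GLY = "G", SER = "S", THR = "T", CYS = "C", ASP = "D",
                 GLU = "E", PHE = "F", HIS = "H", LYS = "K", ASN = "N",
                 GLN = "Q", PRO = "P", ARG = "R", TRP = "W", TYR = "Y")

#' Build a structure object from an atom table
#'
#' Low-level constructor used by \code{\link{read_structure}} and by the
#' synthetic-data generators. Validates that coordinates are finite and that
#' no (chain, residue, atom, altloc) key is duplicated.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{restype}, \code{atom}, \code{x}, \code{y}, \code{z} and
#'   optionally \code{altloc} (defaults to "").
#' @return An object of class \code{nmr_structure}.
#' @export
structure_from_atoms <- function(atoms) {
  need <- c("chain", "resno", "restype", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom, altloc) records")
  structure(list(atoms = atoms[, c(need, "altloc")]), class = "nmr_structure")
}

#' Read a protein structure from PDB or mmCIF
#'
#' Thin wrapper around \code{bio3d::read.pdb} / \code{bio3d::read.cif}.
#' Only ATOM/HETATM records of standard residues are kept. Alternate
#' locations other than blank or 'A' are dropped with a message.
#'
#' @param path path to a .pdb or .cif file.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @return An object of class \code{nmr_structure}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  drop <- !(alt %in% c("", "A"))
  if (any(drop))
    message("dropping ", sum(drop), " atoms with altloc other than ''/'A'")
  a <- a[!drop, , drop = FALSE]
  structure_from_atoms(data.frame(
    chain = a$chain, resno = a$resno, restype = a$resid, atom = a$elety,
    x = a$x, y = a$y, z = a$z, altloc = alt[!drop],
    stringsAsFactors = FALSE))
}

.methyl_id <- function(restype, resno, pseudo) {
  one <- .one_letter[restype]
  one[is.na(one)] <- "X"
  paste0(one, resno, "-", pseudo)
}

# residue part of a methyl id ("L315-QD1" -> "L315")
.methyl_residue <- function(methyl_id) sub("-.*$", "", methyl_id)

#' Enumerate ILVM methyl groups of a chain
#'
#' One row per Ile-delta1, Leu-delta1/delta2, Val-gamma1/gamma2 and
#' Met-epsilon methyl present in the requested chain (Ile-gamma2 only on
#' request). Each methyl carries its carbon coordinate and a pseudo-atom:
#' the geometric centre of the three methyl protons when they are present
#' in the coordinates, otherwise (crystal structures) either the methyl
#' carbon itself (\code{pseudo_mode = "carbon"}, the default fallback) or an
#' idealized proton centroid placed 0.3633 \AA{} beyond the carbon along
#' the bond from the preceding heavy atom (\code{pseudo_mode = "ideal"},
#' from tetrahedral geometry with a 1.09-\AA{} C-H bond).
#'
#' Methyls whose carbon or preceding heavy atom is missing are excluded
#' with a warning. Rows are ordered by residue number, then methyl label.
#'
#' @param structure an \code{nmr_structure}.
#' @param chain chain id (default "A").
#' @param include_ile_gamma2 also enumerate Ile-gamma2 methyls?
#' @param pseudo_mode "auto" (protons when present, else carbon), "carbon",
#'   "ideal" or "protons" (error when protons absent).
#' @return data.frame of class \code{methyl_table} with columns
#'   \code{methyl_id}, \code{chain}, \code{resno}, \code{restype},
#'   \code{label}, \code{stereo}, carbon coordinates \code{cx,cy,cz} and
#'   pseudo-atom coordinates \code{px,py,pz}.
#' @export
extract_methyls <- function(structure, chain = "A",
                            include_ile_gamma2 = FALSE,
                            pseudo_mode = c("auto", "carbon", "ideal",
                                            "protons")) {
  pseudo_mode <- match.arg(pseudo_mode)
  atoms <- structure$atoms
  if (!chain %in% atoms$chain) stop("chain '", chain, "' not in structure")
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  def <- .methyl_def
  if (!include_ile_gamma2)
    def <- def[!(def$restype == "ILE" & def$label == "gamma2"), ]

  res <- unique(atoms[, c("resno", "restype")])
  res <- res[res$restype %in% def$restype, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(res))) {
    rn <- res$resno[i]; rt <- res$restype[i]
    ra <- atoms[atoms$resno == rn & atoms$restype == rt, , drop = FALSE]
    for (j in which(def$restype == rt)) {
      d <- def[j, ]
      carb <- ra[ra$atom == d$carbon, , drop = FALSE]
      prev <- ra[ra$atom == d$prev, , drop = FALSE]
      if (nrow(carb) == 0 || nrow(prev) == 0) {
        warning("incomplete side chain for ", rt, rn, " (", d$label,
                "); methyl excluded", call. = FALSE)
        next
      }
      cc <- c(carb$x[1], carb$y[1], carb$z[1])
      hn <- paste0("H", substring(d$carbon, 2), 1:3)
      hh <- ra[ra$atom %in% hn, , drop = FALSE]
      have_h <- nrow(hh) == 3
      pp <- if (pseudo_mode %in% c("auto", "protons") && have_h) {
        c(mean(hh$x), mean(hh$y), mean(hh$z))
      } else if (pseudo_mode == "protons") {
        stop("methyl protons absent for ", rt, rn, " but pseudo_mode = 'protons'")
      } else if (pseudo_mode == "ideal") {
        v <- cc - c(prev$x[1], prev$y[1], prev$z[1])
        cc + 1.09 * cos(pi * 70.53 / 180) * v / sqrt(sum(v^2))
      } else cc
      out[[length(out) + 1L]] <- data.frame(
        methyl_id = .methyl_id(rt, rn, d$pseudo), chain = chain, resno = rn,
        restype = rt, label = d$label, stereo = d$stereo,
        cx = cc[1], cy = cc[2], cz = cc[3],
        px = pp[1], py = pp[2], pz = pp[3], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    m <- data.frame(methyl_id = character(), chain = character(),
                    resno = integer(), restype = character(),
                    label = character(), stereo = character(),
                    cx = numeric(), cy = numeric(), cz = numeric(),
                    px = numeric(), py = numeric(), pz = numeric(),
                    stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, out)
    m <- m[order(m$resno, m$label), , drop = FALSE]
    rownames(m) <- NULL
  }
  class(m) <- c("methyl_table", "data.frame")
  m
}

#' Pairwise distances between methyl pseudo-atoms
#'
#' @param methyls a methyl table.
#' @param use "pseudo" (default) or "carbon" coordinates.
#' @return symmetric matrix of Euclidean distances (\AA) with methyl ids as
#'   dimnames.
#' @export
methyl_distance_matrix <- function(methyls, use = c("pseudo", "carbon")) {
  use <- match.arg(use)
  if (nrow(methyls) < 1) stop("need at least one methyl")
  xyz <- if (use == "pseudo") cbind(methyls$px, methyls$py, methyls$pz)
         else cbind(methyls$cx, methyls$cy, methyls$cz)
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(methyls$methyl_id, methyls$methyl_id)
  d
}

#' Nearest methyl neighbour
#'
#' Minimum-distance partner of a methyl, optionally excluding methyls on the
#' same residue (the geminal partner). Ties are broken by lower residue
#' number, then label order.
#'
#' @param methyl_id id of the query methyl.
#' @param dmat distance matrix from \code{\link{methyl_distance_matrix}}.
#' @param exclude_same_residue skip methyls of the query's own residue?
#' @return list with \code{methyl_id}, \code{distance} and logical
#'   \code{isolated} (TRUE with \code{methyl_id = NA} when no eligible
#'   partner exists).
#' @export
nearest_methyl <- function(methyl_id, dmat, exclude_same_residue = TRUE) {
  ids <- rownames(dmat)
  if (!methyl_id %in% ids) stop("unknown methyl id: ", methyl_id)
  cand <- setdiff(ids, methyl_id)
  if (exclude_same_residue)
    cand <- cand[.methyl_residue(cand) != .methyl_residue(methyl_id)]
  if (length(cand) == 0)
    return(list(methyl_id = NA_character_, distance = Inf, isolated = TRUE))
  d <- dmat[methyl_id, cand]
  ord <- order(d, as.integer(sub("^[A-Z]([0-9]+)-.*$", "\\1", cand)), cand)
  list(methyl_id = cand[ord[1]], distance = unname(d[ord[1]]),
       isolated = FALSE)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees, range (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("dihedral undefined: collinear atoms")
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Side-chain chi2 dihedral of a Leu or Ile residue
#'
#' Leu: CA-CB-CG-CD1; Ile: CA-CB-CG1-CD1. IUPAC sign convention, range
#' (-180, 180].
#'
#' @param structure an \code{nmr_structure}.
#' @param chain chain id.
#' @param resno residue number.
#' @return chi2 angle in degrees.
#' @export
chi2_dihedral <- function(structure, chain, resno) {
  atoms <- structure$atoms
  ra <- atoms[atoms$chain == chain & atoms$resno == resno, , drop = FALSE]
  if (nrow(ra) == 0) stop("residue not found: ", chain, "/", resno)
  rt <- ra$restype[1]
  names4 <- switch(rt,
    LEU = c("CA", "CB", "CG", "CD1"),
    ILE = c("CA", "CB", "CG1", "CD1"),
    stop("chi2 defined here only for Leu and Ile (got ", rt, ")"))
  pts <- lapply(names4, function(nm) {
    row <- ra[ra$atom == nm, , drop = FALSE]
    if (nrow(row) == 0) stop("missing atom ", nm, " in ", rt, resno)
    c(row$x[1], row$y[1], row$z[1])
  })
  dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Classify a chi2 dihedral into a rotamer bin
#'
#' Half-open 120-degree bins: trans = (120, 180] and (-180, -120];
#' gauche+ = (0, 120]; gauche- = (-120, 0]. Every angle in (-180, 180] maps
#' to exactly one class.
#'
#' @param chi2 angle(s) in degrees, range (-180, 180].
#' @return character vector: "trans", "gauche+" or "gauche-".
#' @export
classify_rotamer <- function(chi2) {
  if (any(chi2 <= -180 | chi2 > 180))
    stop("chi2 must lie in (-180, 180]")
  ifelse(chi2 > 120 | chi2 <= -120, "trans",
         ifelse(chi2 > 0, "gauche+", "gauche-"))
}
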