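# Builders for coarse-grained DNA and protein models, charge rules, and
# in-silico mutations.

# three-letter residue table with default charges at neutral pH
.AA3 <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0, GLU = -1,
          GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1, MET = 0, PHE = 0,
          PRO = 0, SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0)
.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Residue charge rule
#'
#' Default charges at neutral pH: Arg/Lys +1e, Asp/Glu -1e, all others 0.
#' The histidine charge is configurable; termini carry no extra charge.
#'
#' @param resid three-letter residue codes.
#' @param his_charge charge assigned to histidine, e.
#' @return numeric charges in e.
#' @export
residue_charge <- function(resid, his_charge = 0) {
  resid <- toupper(resid)
  unknown <- setdiff(unique(resid), names(.AA3))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  ch <- .AA3[resid]
  ch[resid == "HIS"] <- his_charge
  unname(ch)
}

# geometry of the CG duplex (nm / degrees); phosphate azimuths are constants
# in each base-pair frame, so consecutive phosphates trace the two helical
# backbones
.DNA_GEOM <- list(core_radius = 0.8, phosphate_radius = 0.25,
                  backbone_radius = 0.9, phosphate_azimuth = 1.658)

.DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

validate_sequence <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 1) stop("sequence must have length >= 1")
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("sequence must use the alphabet {A, C, G, T}")
  bases
}

#' Build a coarse-grained DNA duplex
#'
#' Rigid base-pair model with explicit phosphate charge beads.  Each base
#' pair becomes one rigid unit (a neutral core bead on the helical axis plus
#' its backbone phosphates) placed on an ideal straight B-DNA helix; each of
#' the 2(N-1) internucleotide linkages carries one phosphate bead of charge
#' -1e at the canonical backbone radius (5'-terminal phosphates are absent,
#' so a duplex of N base pairs has net charge -2(N-1) e).  Consecutive units
#' are coupled by the quadratic base-pair step elasticity in `params`.
#'
#' @param sequence nucleotide sequence (one strand, 5'->3'), alphabet ACGT.
#' @param params a [bp_step_params()] object.
#' @param frames optional non-ideal base-pair frames: list with `origin`
#'   (N x 3) and `R` (N x 9 row-major rotations); default ideal B-DNA.
#' @return a DNA `cg_structure`.
#' @examples
#' dna <- build_dna_cg(strrep("AT", 21))  # 42 bp
#' net_charge(dna)                        # -82
#' @export
build_dna_cg <- function(sequence, params = bp_step_params(), frames = NULL) {
  bases <- validate_sequence(sequence)
  n <- length(bases)
  twist <- params$rest_step[["twist"]] * pi / 180
  rise <- params$rest_step[["rise"]]
  if (is.null(frames)) {
    origin <- cbind(0, 0, (seq_len(n) - 1) * rise)
    Rm <- matrix(0, n, 9)
    for (i in seq_len(n)) {
      a <- (i - 1) * twist
      Rm[i, ] <- c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1)
    }
    frames <- list(origin = origin, R = Rm)
  } else {
    if (nrow(frames$origin) != n) stop("frames must supply one frame per bp")
  }
  g <- .DNA_GEOM
  # core beads (one per bp, on the axis)
  core <- data.frame(
    index = seq_len(n),
    label = paste0(bases, .DNA_COMPLEMENT[bases]),
    resno = seq_len(n),
    x = frames$origin[, 1], y = frames$origin[, 2], z = frames$origin[, 3],
    radius = g$core_radius, charge = 0, group = "bp",
    stringsAsFactors = FALSE)
  bead_body <- seq_len(n)
  beads <- core
  if (n > 1) {
    # phosphates: strand I linkage j->j+1 assigned to body j+1 (its
    # 5'-phosphate); strand II (antiparallel) linkage assigned to body j
    loc1 <- c(g$backbone_radius * cos(g$phosphate_azimuth),
              g$backbone_radius * sin(g$phosphate_azimuth), -rise / 2)
    loc2 <- c(g$backbone_radius * cos(-g$phosphate_azimuth),
              g$backbone_radius * sin(-g$phosphate_azimuth), rise / 2)
    ph <- vector("list", 2 * (n - 1))
    for (j in seq_len(n - 1)) {
      b1 <- j + 1
      R1 <- matrix(frames$R[b1, ], 3, 3, byrow = TRUE)
      p1 <- frames$origin[b1, ] + drop(R1 %*% loc1)
      b2 <- j
      R2 <- matrix(frames$R[b2, ], 3, 3, byrow = TRUE)
      p2 <- frames$origin[b2, ] + drop(R2 %*% loc2)
      ph[[2 * j - 1]] <- data.frame(index = 0, label = "P_I", resno = b1,
                                    x = p1[1], y = p1[2], z = p1[3],
                                    radius = g$phosphate_radius, charge = -1,
                                    group = "phosphate")
      ph[[2 * j]] <- data.frame(index = 0, label = "P_II", resno = b2,
                                x = p2[1], y = p2[2], z = p2[3],
                                radius = g$phosphate_radius, charge = -1,
                                group = "phosphate")
      bead_body <- c(bead_body, b1, b2)
    }
    beads <- rbind(beads, do.call(rbind, ph))
    beads$index <- seq_len(nrow(beads))
  }
  steps <- if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL
  cg_structure(beads,
               bodies = list(origin = frames$origin, R = frames$R,
                             bead_body = bead_body),
               steps = steps, molecule = "dna",
               sequence = paste(bases, collapse = ""), params = params)
}

#' Build a coarse-grained protein model
#'
#' One bead per residue at the alpha-carbon position, harmonic springs
#' between all bead pairs within `cutoff` at their observed distances
#' (elastic network), and integer charges from the residue type
#' ([residue_charge()]).
#'
#' @param x either a path to a PDB file, a `bio3d` pdb object, or an
#'   n x 3 coordinate matrix in nm (then `resno`/`resid` are required).
#' @param resno author residue numbers (for matrix input).
#' @param resid three-letter residue codes (for matrix input).
#' @param cutoff elastic-network cutoff, nm.
#' @param k_spring spring constant, kJ/mol/nm^2.
#' @param his_charge histidine charge, e.
#' @param radius bead radius, nm.
#' @param chain chain to use when reading a PDB with several chains.
#' @return a protein `cg_structure`.
#' @export
build_protein_cg <- function(x, resno = NULL, resid = NULL, cutoff = 1.0,
                             k_spring = 500, his_charge = 0, radius = 0.35,
                             chain = NULL) {
  if (is.character(x) && length(x) == 1) x <- bio3d::read.pdb(x)
  if (inherits(x, "pdb")) {
    sel <- bio3d::atom.select(x, "calpha", verbose = FALSE)
    at <- x$atom[sel$atom, ]
    if (!is.null(chain)) at <- at[at$chain %in% chain, ]
    if (nrow(at) == 0) stop("no alpha-carbon coordinates found")
    xyz <- as.matrix(at[, c("x", "y", "z")]) / 10  # Angstrom -> nm
    resno <- at$resno
    resid <- at$resid
  } else {
    xyz <- matrix(as.numeric(x), ncol = 3)
    if (is.null(resno)) resno <- seq_len(nrow(xyz))
    if (is.null(resid)) stop("resid (residue codes) required for matrix input")
    resid <- toupper(resid)
    one <- nchar(resid) == 1
    resid[one] <- .AA1TO3[resid[one]]
    if (any(is.na(resid))) stop("unknown residue code in resid")
  }
  if (any(!complete.cases(xyz))) {
    bad <- resno[!complete.cases(xyz)]
    stop("missing coordinates for residue(s): ", paste(bad, collapse = ", "))
  }
  if (length(resid) != nrow(xyz) || length(resno) != nrow(xyz))
    stop("resno/resid must match the number of residues")
  charge <- residue_charge(resid, his_charge)
  n <- nrow(xyz)
  beads <- data.frame(index = seq_len(n), label = toupper(resid),
                      resno = resno,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = radius, charge = charge, group = "residue",
                      stringsAsFactors = FALSE)
  dm <- as.matrix(dist(xyz))
  pairs <- which(upper.tri(dm) & dm <= cutoff & dm > 0, arr.ind = TRUE)
  springs <- if (nrow(pairs)) {
    data.frame(i = pairs[, 1], j = pairs[, 2],
               r0 = dm[pairs], k = k_spring)
  } else NULL
  cg_structure(beads, springs = springs, molecule = "protein")
}

#' Apply an in-silico point mutation
#'
#' Replaces the residue at an author residue number with a new residue type,
#' updating the bead label and charge; geometry and the elastic network are
#' unchanged.
#'
#' @param structure a protein `cg_structure`.
#' @param resno author residue number(s) to mutate.
#' @param target target residue code (one- or three-letter), recycled.
#' @param his_charge histidine charge convention, e.
#' @return a new `cg_structure`.
#' @examples
#' \dontrun{
#' mut <- apply_mutation(a1, c(1392, 1395, 1399), "E")  # triple R -> E
#' }
#' @export
apply_mutation <- function(structure, resno, target, his_charge = 0) {
  stopifnot(inherits(structure, "cg_structure"))
  if (structure$molecule != "protein")
    stop("mutations apply to protein structures")
  target <- toupper(target)
  target <- ifelse(nchar(target) == 1, .AA1TO3[target], target)
  if (any(is.na(target)) || !all(target %in% names(.AA3)))
    stop("unknown target residue code")
  target <- rep_len(target, length(resno))
  for (k in seq_along(resno)) {
    hit <- structure$beads$group == "residue" & structure$beads$resno == resno[k]
    if (!any(hit)) stop("residue number not found: ", resno[k])
    structure$beads$label[hit] <- target[k]
    structure$beads$charge[hit] <- residue_charge(target[k], his_charge)
  }
  structure
}

#' Binding-region map of the vWF A1 domain
#'
#' Author-numbered residue sets used to classify protein-DNA contacts: the
#' arginine triad on helix H4 (region 1), the distal arginine R1336 (region
#' 2), and the adjacent lysine patch K1405-K1408.
#'
#' @param region1,region2,lysine_patch author residue numbers.
#' @return object of class `region_map`.
#' @export
region_map_a1 <- function(region1 = c(1392, 1395, 1399), region2 = 1336,
                          lysine_patch = 1405:1408) {
  sets <- list(region1 = region1, region2 = region2,
               lysine_patch = lysine_patch)
  all_res <- unlist(sets)
  if (anyDuplicated(all_res)) stop("region sets must be pairwise disjoint")
  structure(sets, class = "region_map")
}
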