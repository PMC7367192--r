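# The cg_structure container: beads, springs, rigid bodies, step topology.

#' Construct a coarse-grained structure
#'
#' Low-level constructor.  Most users build structures with [build_dna_cg()],
#' [build_protein_cg()], [generate_bdna()] or [generate_mock_a1()].
#'
#' @param beads data frame with columns `index`, `label`, `resno`, `x`, `y`,
#'   `z` (nm), `radius` (nm), `charge` (e), `group`.
#' @param springs data frame with columns `i`, `j`, `r0` (nm), `k`
#'   (kJ/mol/nm^2); `j = 0` anchors bead `i` to its initial position.
#' @param bodies rigid-body definition: list with `origin` (B x 3 matrix),
#'   `R` (B x 9 matrix, row-major rotation matrices) and `bead_body`
#'   (integer per bead; 0 = free bead).
#' @param steps integer matrix of consecutive rigid-body pairs carrying
#'   base-pair step elasticity.
#' @param molecule one of "dna", "protein", "generic".
#' @param sequence nucleotide sequence (DNA structures).
#' @param params the [bp_step_params()] of a DNA structure.
#' @return object of class `cg_structure`.
#' @export
cg_structure <- function(beads, springs = NULL, bodies = NULL, steps = NULL,
                         molecule = c("generic", "dna", "protein"),
                         sequence = NULL, params = NULL) {
  molecule <- match.arg(molecule)
  beads <- as.data.frame(beads)
  need <- c("index", "label", "resno", "x", "y", "z", "radius", "charge", "group")
  miss <- setdiff(need, names(beads))
  if (length(miss)) stop("beads lacks columns: ", paste(miss, collapse = ", "))
  if (any(beads$radius <= 0)) stop("bead radii must be > 0")
  if (!is.null(springs)) {
    springs <- as.data.frame(springs)
    bad <- springs$i < 1 | springs$i > nrow(beads) |
      springs$j < 0 | springs$j > nrow(beads)
    if (any(bad)) stop("spring endpoints must reference existing beads")
  }
  if (!is.null(bodies)) {
    bb <- bodies$bead_body
    if (length(bb) != nrow(beads)) stop("bead_body must map every bead")
    if (any(bb < 0 | bb > nrow(bodies$origin)))
      stop("bead_body references unknown rigid body")
  }
  structure(list(beads = beads, springs = springs, bodies = bodies,
                 steps = steps, molecule = molecule, sequence = sequence,
                 params = params),
            class = "cg_structure")
}

#' Net charge of a CG structure
#'
#' @param x a `cg_structure`.
#' @return net charge in e (sum of bead charges).
#' @export
net_charge <- function(x) {
  stopifnot(inherits(x, "cg_structure"))
  sum(x$beads$charge)
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("CG %s structure: %d beads, net charge %+g e\n",
              x$molecule, nrow(x$beads), net_charge(x)))
  if (!is.null(x$springs))
    cat(sprintf("  %d elastic-network springs\n", nrow(x$springs)))
  if (!is.null(x$bodies))
    cat(sprintf("  %d rigid bodies", nrow(x$bodies$origin)),
        if (!is.null(x$steps)) sprintf("(%d elastic steps)", nrow(x$steps)),
        "\n")
  if (!is.null(x$sequence))
    cat(sprintf("  sequence: %s\n", x$sequence))
  invisible(x)
}

#' Bead coordinates of a CG structure
#'
#' @param x a `cg_structure`.
#' @return n x 3 numeric matrix of bead positions (nm).
#' @export
coords_matrix <- function(x) as.matrix(x$beads[, c("x", "y", "z")])

# centre of geometry
cog <- function(x) colMeans(coords_matrix(x))

# apply a proper rigid motion x -> R (x - about) + about + shift
#' Rigid transform of a CG structure
#'
#' Rotates a structure about a point and translates it, keeping rigid-body
#' frames consistent.
#'
#' @param x a `cg_structure`.
#' @param R 3x3 proper rotation matrix.
#' @param shift length-3 translation (nm).
#' @param about rotation centre (default: centre of geometry).
#' @return the transformed `cg_structure`.
#' @export
transform_cg <- function(x, R = diag(3), shift = c(0, 0, 0), about = cog(x)) {
  stopifnot(inherits(x, "cg_structure"))
  xyz <- coords_matrix(x)
  xyz <- sweep(xyz, 2, about)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, about + shift, FUN = "+")
  x$beads$x <- xyz[, 1]; x$beads$y <- xyz[, 2]; x$beads$z <- xyz[, 3]
  if (!is.null(x$bodies)) {
    o <- x$bodies$origin
    o <- sweep(o, 2, about)
    o <- o %*% t(R)
    x$bodies$origin <- sweep(o, 2, about + shift, FUN = "+")
    for (b in seq_len(nrow(x$bodies$R))) {
      Rb <- matrix(x$bodies$R[b, ], 3, 3, byrow = TRUE)
      x$bodies$R[b, ] <- as.vector(t(R %*% Rb))
    }
  }
  x
}

# random uniform rotation matrix (quaternion method), uses the R RNG
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Ad-hoc bead system
#'
#' Builds a minimal `cg_structure` from raw bead positions, for toy systems
#' and tests (free beads, optional springs).
#'
#' @param xyz n x 3 matrix of positions (nm).
#' @param radius bead radii (recycled), nm.
#' @param charge bead charges (recycled), e.
#' @param springs optional spring data frame (`i`, `j`, `r0`, `k`).
#' @param label bead labels.
#' @return a `cg_structure` with molecule type "generic".
#' @export
bead_system <- function(xyz, radius = 0.3, charge = 0, springs = NULL,
                        label = "X") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  beads <- data.frame(index = seq_len(n),
                      label = rep_len(label, n),
                      resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = rep_len(radius, n),
                      charge = rep_len(charge, n),
                      group = "bead")
  cg_structure(beads, springs = springs, molecule = "generic")
}
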