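#' Built-in species parameter table
#'
#' Per-species bead parameters: mass (amu), Lennard-Jones sigma (A) and
#' epsilon (kcal/mol), intrinsic Born radius rho (A) and formal charge (e).
#' Ion intrinsic radii default to sigma/2; the phosphate pseudo-bead uses
#' rho = 2.0 A. These are literature-magnitude stand-ins for single-bead
#' models (CoHex3+ is one rigid +3e sphere) and can be overridden per
#' particle when building a system.
#'
#' @return data.frame with columns species, class, charge, mass, sigma,
#'   eps_lj, rho.
#' @export
species_table <- function() {
  data.frame(
    species = c("NA", "K", "CL", "COHEX", "P"),
    class   = c("cation", "cation", "anion", "cation", "solute"),
    charge  = c(1, 1, -1, 3, -1),
    mass    = c(22.99, 39.10, 35.45, 161.1, 94.97),
    sigma   = c(2.45, 3.04, 4.40, 6.20, 4.00),
    eps_lj  = c(0.0874, 0.10, 0.10, 0.20, 0.20),
    rho     = c(1.225, 1.52, 2.20, 3.10, 2.00),
    stringsAsFactors = FALSE
  )
}

# intrinsic radii for common elements in all-atom PDB input (mbondi3-like)
.element_radii <- c(H = 1.30, C = 1.70, N = 1.55, O = 1.50, P = 1.85, S = 1.80)

#' Build a validated particle system
#'
#' The central container for all energy and dynamics routines: particle
#' positions (A), charges (e), intrinsic Born radii (A), Lennard-Jones
#' parameters, a topology class (`solute`, `cation`, or `anion`), a species
#' label, a mobility flag, and a mass (amu).
#'
#' @param records data.frame with columns `x`, `y`, `z`, `charge`, `rho`,
#'   `class`, and optionally `sigma`, `eps_lj`, `species`, `mobility`,
#'   `mass`. Missing optional columns are filled with defaults (sigma =
#'   2*rho, eps_lj = 0.1, species = "X", mobility = "free" for ions /
#'   "fixed" for solute, mass = 40).
#' @return An object of class `particle_system`: a list with matrix `pos`
#'   (n x 3) and per-particle vectors `charge`, `rho`, `sigma`, `eps_lj`,
#'   `class`, `species`, `mobility`, `mass`.
#' @examples
#' sys <- particle_system(data.frame(x = 0, y = 0, z = 0, charge = 1,
#'                                   rho = 1.5, class = "cation"))
#' net_charge(sys)
#' @export
particle_system <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n < 1) stop("a particle system needs at least one particle")
  need <- c("x", "y", "z", "charge", "rho", "class")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing record columns: ", paste(miss, collapse = ", "))

  pos <- as.matrix(records[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  storage.mode(pos) <- "double"
  if (any(!is.finite(pos))) {
    bad <- which(rowSums(!is.finite(pos)) > 0)[1]
    stop("non-finite coordinate at particle index ", bad)
  }
  rho <- as.numeric(records$rho)
  if (any(!is.finite(rho) | rho <= 0)) {
    bad <- which(!is.finite(rho) | rho <= 0)[1]
    stop("non-positive intrinsic radius at particle index ", bad)
  }
  cls <- as.character(records$class)
  .class_code(cls)  # errors with index on unknown class

  sigma <- if ("sigma" %in% names(records)) as.numeric(records$sigma) else 2 * rho
  if (any(!is.finite(sigma) | sigma <= 0)) {
    bad <- which(!is.finite(sigma) | sigma <= 0)[1]
    stop("non-positive Lennard-Jones sigma at particle index ", bad)
  }
  eps_lj <- if ("eps_lj" %in% names(records)) as.numeric(records$eps_lj) else rep(0.1, n)
  species <- if ("species" %in% names(records)) as.character(records$species) else rep("X", n)
  mobility <- if ("mobility" %in% names(records)) as.character(records$mobility)
              else ifelse(cls == "solute", "fixed", "free")
  if (!all(mobility %in% c("fixed", "restrained", "free")))
    stop("mobility must be one of fixed/restrained/free")
  mass <- if ("mass" %in% names(records)) as.numeric(records$mass) else {
    st <- species_table()
    m <- st$mass[match(species, st$species)]
    m[is.na(m)] <- 40
    m
  }

  structure(list(pos = pos, charge = as.numeric(records$charge), rho = rho,
                 sigma = sigma, eps_lj = eps_lj, class = cls,
                 species = species, mobility = mobility, mass = mass,
                 meta = list()),
            class = "particle_system")
}

#' Number of particles in a system
#' @param system a `particle_system`.
#' @return integer count.
#' @export
n_particles <- function(system) nrow(system$pos)

#' Net charge of a system
#' @param system a `particle_system`.
#' @return total charge in e.
#' @export
net_charge <- function(system) sum(system$charge)

#' Per-class particle counts
#' @param system a `particle_system`.
#' @return named integer vector over solute/cation/anion.
#' @export
class_counts <- function(system) {
  vapply(.topo_classes, function(k) sum(system$class == k), integer(1))
}

#' @export
print.particle_system <- function(x, ...) {
  cc <- class_counts(x)
  cat("particle_system:", n_particles(x), "particles",
      sprintf("(solute %d, cation %d, anion %d)\n", cc[1], cc[2], cc[3]))
  cat("  net charge:", format(net_charge(x)), "e\n")
  cat("  species:", paste(unique(x$species), collapse = ", "), "\n")
  mobile <- sum(x$mobility != "fixed")
  cat("  mobile particles:", mobile, "\n")
  invisible(x)
}

# combine two systems (used when adding ions to a solute)
.bind_systems <- function(a, b) {
  structure(list(pos = rbind(a$pos, b$pos),
                 charge = c(a$charge, b$charge),
                 rho = c(a$rho, b$rho),
                 sigma = c(a$sigma, b$sigma),
                 eps_lj = c(a$eps_lj, b$eps_lj),
                 class = c(a$class, b$class),
                 species = c(a$species, b$species),
                 mobility = c(a$mobility, b$mobility),
                 mass = c(a$mass, b$mass),
                 meta = a$meta),
            class = "particle_system")
}

# data.frame view of a system
.system_records <- function(system) {
  data.frame(x = system$pos[, 1], y = system$pos[, 2], z = system$pos[, 3],
             charge = system$charge, rho = system$rho, sigma = system$sigma,
             eps_lj = system$eps_lj, class = system$class,
             species = system$species, mobility = system$mobility,
             mass = system$mass, stringsAsFactors = FALSE)
}
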