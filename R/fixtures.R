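# Synthetic-system generators: the idealized B-DNA phosphate lattice, random
# ion placement, and toy systems used throughout the tests.

#' Idealized B-form DNA phosphate model
#'
#' Coarse double-helical polyelectrolyte: one -1e pseudo-bead per backbone
#' phosphate on two strands of an ideal B-form helix (radius 8.9 A, rise
#' 3.4 A per bp, twist 36 degrees per bp, strand azimuthal offset 154
#' degrees — the minor-groove convention). Each strand carries n_bp - 1
#' phosphates (uncharged 5' terminus), so the total charge is
#' -2 (n_bp - 1) e: -48e for 25 bp, -22e for 12 bp. The helix axis is the
#' z axis, centred on the origin; the nominal axial length n_bp * rise is
#' recorded in the system metadata (85 A for 25 bp).
#'
#' @param n_bp number of base pairs (>= 2).
#' @param radius phosphate strand radius in A.
#' @param rise rise per base pair in A.
#' @param twist twist per base pair in degrees.
#' @param strand_offset azimuthal offset between strands in degrees.
#' @param rho intrinsic Born radius of the phosphate bead in A.
#' @param sigma,eps_lj Lennard-Jones parameters of the bead.
#' @param mobility "fixed" (default) or "restrained".
#' @return a [particle_system()] of 2 (n_bp - 1) solute beads.
#' @examples
#' dna <- build_bdna(25)
#' net_charge(dna)  # -48
#' @export
build_bdna <- function(n_bp, radius = 8.9, rise = 3.4, twist = 36,
                       strand_offset = 154, rho = 2.0, sigma = 4.0,
                       eps_lj = 0.2, mobility = "fixed") {
  if (n_bp < 2) stop("n_bp must be >= 2")
  k <- seq_len(n_bp - 1)
  z <- (k - n_bp / 2) * rise
  th_a <- k * twist * pi / 180
  th_b <- th_a + strand_offset * pi / 180
  rec <- data.frame(
    x = c(radius * cos(th_a), radius * cos(th_b)),
    y = c(radius * sin(th_a), radius * sin(th_b)),
    z = c(z, z),
    charge = -1, rho = rho, sigma = sigma, eps_lj = eps_lj,
    class = "solute", species = "P", mobility = mobility,
    mass = 94.97, stringsAsFactors = FALSE)
  sys <- particle_system(rec)
  sys$meta <- list(kind = "bdna", n_bp = n_bp, axis_length = n_bp * rise,
                   radius = radius, rise = rise, twist = twist,
                   strand_offset = strand_offset)
  sys
}

#' Place ions uniformly at random inside a restraint sphere
#'
#' Adds the requested ions at uniform random positions inside the sphere,
#' rejecting any draw closer than `min_dist` to an already placed particle.
#' Deterministic for a fixed seed (the global RNG state is restored on
#' exit).
#'
#' @param system a [particle_system()] (may be empty of ions).
#' @param species_counts named integer vector, e.g. `c("NA" = 36, CL = 14)`;
#'   names must exist in [species_table()].
#' @param sphere a [restraint_spec()] or list with `anchor` (xyz) and `r3`.
#' @param seed RNG seed.
#' @param min_dist minimum interparticle distance in A.
#' @param max_tries placement attempts per ion before giving up.
#' @return the enlarged [particle_system()].
#' @export
place_ions <- function(system, species_counts, sphere, seed = 1,
                       min_dist = 2.5, max_tries = 2000) {
  stopifnot(inherits(system, "particle_system"))
  if (any(species_counts < 0)) stop("ion counts must be >= 0")
  if (sum(species_counts) == 0) return(system)
  st <- species_table()
  unknown <- setdiff(names(species_counts), st$species)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  center <- if (is.numeric(sphere$anchor)) sphere$anchor else c(0, 0, 0)
  r3 <- sphere$r3

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  existing <- system$pos
  rows <- list()
  for (sp in names(species_counts)) {
    prm <- st[st$species == sp, ]
    for (m in seq_len(species_counts[[sp]])) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        # uniform in the ball by radius inversion
        u <- runif(3)
        r <- r3 * u[1]^(1 / 3)
        ct <- 2 * u[2] - 1
        ph <- 2 * pi * u[3]
        p <- center + r * c(sqrt(1 - ct^2) * cos(ph),
                            sqrt(1 - ct^2) * sin(ph), ct)
        if (nrow(existing) == 0 ||
            min(sqrt(rowSums(sweep(existing, 2, p)^2))) >= min_dist) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a ", sp, " ion after ", max_tries,
             " attempts (sphere too crowded?)")
      rows[[length(rows) + 1]] <- data.frame(
        x = p[1], y = p[2], z = p[3], charge = prm$charge, rho = prm$rho,
        sigma = prm$sigma, eps_lj = prm$eps_lj, class = prm$class,
        species = sp, mobility = "free", mass = prm$mass,
        stringsAsFactors = FALSE)
      existing <- rbind(existing, matrix(p, 1))
    }
  }
  ions <- particle_system(do.call(rbind, rows))
  .bind_systems(system, ions)
}
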