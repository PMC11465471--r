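# PDB input/output (via bio3d) in the package's fixture dialect:
# pseudo-particles are HETATM records, the occupancy column carries the
# charge (e) and the B-factor column the intrinsic Born radius (A).

#' Write a particle system as a PDB file
#'
#' HETATM records with the species label as atom/residue name; occupancy =
#' charge, B-factor = intrinsic radius (documented dialect). Output is
#' byte-deterministic for identical systems.
#'
#' @param system a [particle_system()].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_pdb <- function(system, path) {
  stopifnot(inherits(system, "particle_system"))
  n <- n_particles(system)
  xyz <- as.vector(t(system$pos))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("HETATM", n),
                   resno = seq_len(n),
                   resid = substr(system$species, 1, 3),
                   eleno = seq_len(n),
                   elety = substr(system$species, 1, 4),
                   chain = ifelse(system$class == "solute", "A", "B"),
                   o = system$charge, b = system$rho,
                   elesy = substr(system$species, 1, 2))
  invisible(path)
}

#' Read a particle system from a PDB file
#'
#' Coordinates and names are parsed with bio3d; charges, radii, masses and
#' Lennard-Jones parameters are attached from [species_table()] when the
#' atom name matches a known species, and from a small built-in element
#' radius table otherwise. In the fixture dialect (default) the occupancy
#' column overrides the charge and the B-factor the intrinsic radius.
#'
#' @param path PDB file.
#' @param charges_from_occupancy read charges from the occupancy column
#'   (the fixture dialect); set FALSE for third-party PDB files, in which
#'   case charges default to the species' formal charge or 0.
#' @return a [particle_system()].
#' @export
read_pdb <- function(path, charges_from_occupancy = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms in PDB file: ", path)
  st <- species_table()
  sp <- trimws(at$elety)
  m <- match(sp, st$species)

  cls <- ifelse(is.na(m), "solute", st$class[m])
  charge <- ifelse(is.na(m), 0, st$charge[m])
  rho <- ifelse(is.na(m), NA_real_, st$rho[m])
  sigma <- ifelse(is.na(m), NA_real_, st$sigma[m])
  eps_lj <- ifelse(is.na(m), 0.1, st$eps_lj[m])
  mass <- ifelse(is.na(m), 40, st$mass[m])

  # unknown species: element-based intrinsic radii
  if (anyNA(rho)) {
    el <- toupper(substr(trimws(ifelse(nzchar(trimws(at$elesy)), at$elesy, sp)), 1, 1))
    er <- .element_radii[el]
    er[is.na(er)] <- 1.7
    rho[is.na(rho)] <- er[is.na(rho)]
    sigma[is.na(sigma)] <- 2 * rho[is.na(sigma)]
  }
  if (charges_from_occupancy && !all(is.na(at$o))) charge <- at$o
  if (!all(is.na(at$b)) && all(at$b[!is.na(at$b)] > 0)) rho <- at$b

  particle_system(data.frame(
    x = at$x, y = at$y, z = at$z, charge = charge, rho = rho,
    sigma = sigma, eps_lj = eps_lj, class = cls, species = sp,
    mobility = ifelse(cls == "solute", "fixed", "free"),
    mass = mass, stringsAsFactors = FALSE))
}
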