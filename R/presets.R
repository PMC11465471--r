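# Preset ion-parameter sets and their flat key:value file format.
#
# AMBER-style key aliases map onto the pair-class table as
#   gamma(a,b)  = 4 * gi_coef_*      (K_GB scales the canonical exponent 4)
#   eps_in(a,b) = intdiel_ion_*      (K_eps is the internal dielectric)
# with suffixes: _p = (solute,cation), _n = (solute,anion), _pp =
# (cation,cation), _pn = (anion,cation), _nn = (anion,anion).

.preset_files <- c("NaCl-DNA" = "nacl_dna.preset",
                   "KCl-DNA" = "kcl_dna.preset",
                   "CoHex-DNA" = "cohex_dna.preset")

#' List available parameter presets
#' @return character vector of preset names.
#' @export
list_presets <- function() names(.preset_files)

#' Read a flat key:value preset file
#'
#' @param path path to a preset file: one `key: value` pair per line,
#'   `#` comments allowed. Recognized keys are the AMBER-style coefficient
#'   aliases (`gi_coef_1_p`, `intdiel_ion_1_pn`, ...) plus `cation` and
#'   `anion` species labels.
#' @return list with `pair_table` (a [pair_class_table()]), `cation`,
#'   `anion` (species labels) and `raw` (the parsed key/value pairs).
#' @export
read_preset <- function(path) {
  if (!file.exists(path)) stop("preset file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed preset line: '", lines[which(bad)[1]], "'")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  raw <- as.list(vals)
  names(raw) <- keys

  suffix_pair <- c(p = "sc", n = "sa", pp = "cc", pn = "ca", nn = "aa")
  gamma <- c(ss = 4); eps_in <- c(ss = 1)
  for (sfx in names(suffix_pair)) {
    gk <- paste0("gi_coef_1_", sfx)
    ek <- paste0("intdiel_ion_1_", sfx)
    if (!is.null(raw[[gk]]))
      gamma[suffix_pair[sfx]] <- 4 * as.numeric(raw[[gk]])
    if (!is.null(raw[[ek]]))
      eps_in[suffix_pair[sfx]] <- as.numeric(raw[[ek]])
  }
  tab <- pair_class_table(gamma = gamma, eps_in = eps_in)
  list(pair_table = tab,
       cation = if (!is.null(raw$cation)) raw$cation else NA_character_,
       anion = if (!is.null(raw$anion)) raw$anion else NA_character_,
       raw = raw)
}

#' Load a named ion-parameter preset
#'
#' Ships three presets matching the model's published parameterizations:
#' `NaCl-DNA`, `KCl-DNA` (identical except eps_in(s,c) = eps_in(c,c) = 36
#' instead of 54), and `CoHex-DNA` (trivalent cobalt hexammine with
#' near-Coulomb solute-cation coupling).
#'
#' @param name preset name, see [list_presets()].
#' @return list as from [read_preset()], plus `name` and species parameter
#'   rows `cation_params`/`anion_params` from [species_table()].
#' @examples
#' p <- preset_species("NaCl-DNA")
#' pair_class_lookup(p$pair_table, "anion", "cation")  # gamma 0.2, eps_in 8
#' @export
preset_species <- function(name) {
  if (!name %in% names(.preset_files))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.preset_files), collapse = ", "))
  path <- system.file("extdata", .preset_files[[name]], package = "gbion")
  p <- read_preset(path)
  st <- species_table()
  p$name <- name
  p$cation_params <- st[st$species == p$cation, , drop = FALSE]
  p$anion_params <- st[st$species == p$anion, , drop = FALSE]
  p
}
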