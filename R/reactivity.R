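#' @title Conceptual-DFT global reactivity descriptors
#' @name reactivity
#' @description
#' Global reactivity indices of a compound computed from the vertical/adiabatic
#' ionization potential (IP) and electron affinity (EA), themselves obtained
#' either from total energies of the neutral, cation-radical and anion-radical
#' species or from frontier-orbital energies via the Koopmans approximation
#' (IP = -eps_HOMO, EA = -eps_LUMO).
#'
#' Definitions used throughout (all energies in eV):
#' \itemize{
#'   \item IP  = E(A+) - E(A)
#'   \item EA  = E(A)  - E(A-)
#'   \item gap = EA - IP (signed; \code{abs_gap} gives the conventional
#'         positive HOMO-LUMO gap |IP - EA|)
#'   \item hardness  eta = (IP - EA) / 2
#'   \item softness  S   = 1 / (2 eta)
#'   \item electronegativity chi = (IP + EA) / 2
#'   \item electrophilicity  omega = chi^2 / (2 eta)
#' }
NULL

## Fixed conversion, CODATA-style value used by quantum-chemistry packages.
HARTREE_TO_EV <- 27.211386

#' Species energy set for one compound
#'
#' Bundle of total electronic energies (or enthalpies -- the calculator is
#' agnostic to which energy column the user supplies) of the neutral species
#' A, the cation radical A+ and the anion radical A-.
#'
#' @param compound_id character label.
#' @param E_neutral,E_cation,E_anion finite energies, all in `unit`.
#' @param unit `"eV"` or `"Hartree"`.
#' @return Object of class `species_energy_set`.
#' @examples
#' s <- species_energy_set("cpd1", -423.70, -423.42, -423.76, unit = "Hartree")
#' compute_ip(s)
#' @export
species_energy_set <- function(compound_id, E_neutral, E_cation, E_anion,
                               unit = c("eV", "Hartree")) {
  unit <- match.arg(unit)
  e <- c(E_neutral, E_cation, E_anion)
  if (length(e) != 3L || !all(is.finite(e)))
    stop("species_energy_set: all three energies must be finite numbers")
  structure(list(compound_id = as.character(compound_id)[1],
                 E_neutral = as.numeric(E_neutral),
                 E_cation = as.numeric(E_cation),
                 E_anion = as.numeric(E_anion),
                 unit = unit),
            class = "species_energy_set")
}

#' Frontier-orbital energies for one compound
#'
#' @param compound_id character label.
#' @param eps_homo,eps_lumo HOMO and LUMO energies in eV. A HOMO above the
#'   LUMO is physically meaningless and triggers a warning (not an error).
#' @return Object of class `frontier_orbitals`.
#' @export
frontier_orbitals <- function(compound_id, eps_homo, eps_lumo) {
  if (!is.finite(eps_homo) || !is.finite(eps_lumo))
    stop("frontier_orbitals: orbital energies must be finite")
  if (eps_homo > eps_lumo)
    warning("frontier_orbitals: eps_homo > eps_lumo; input is physically questionable")
  structure(list(compound_id = as.character(compound_id)[1],
                 eps_homo = as.numeric(eps_homo),
                 eps_lumo = as.numeric(eps_lumo)),
            class = "frontier_orbitals")
}

to_ev <- function(x, unit) if (unit == "Hartree") x * HARTREE_TO_EV else x

#' Ionization potential from species energies
#'
#' IP = E(A+) - E(A), returned in eV regardless of the declared input unit.
#'
#' @param species a [species_energy_set()].
#' @return Ionization potential in eV.
#' @export
compute_ip <- function(species) {
  stopifnot(inherits(species, "species_energy_set"))
  to_ev(species$E_cation - species$E_neutral, species$unit)
}

#' Electron affinity from species energies
#'
#' EA = E(A) - E(A-), in eV: positive when the anion is bound (electron
#' attachment releases energy). This is the standard adiabatic electron
#' affinity convention.
#'
#' @param species a [species_energy_set()].
#' @return Electron affinity in eV.
#' @export
compute_ea <- function(species) {
  stopifnot(inherits(species, "species_energy_set"))
  to_ev(species$E_neutral - species$E_anion, species$unit)
}

#' Reactivity descriptors from IP and EA
#'
#' Computes the signed gap (EA - IP), hardness eta = (IP - EA)/2, softness
#' S = 1/(2 eta), electronegativity chi = (IP + EA)/2 and electrophilicity
#' omega = chi^2/(2 eta). When eta == 0 (IP == EA) softness and omega are
#' undefined: they are returned as `NA` with a classed warning
#' (`pocketfp_degenerate_hardness`); all other fields are still returned.
#'
#' @param IP,EA finite energies in eV.
#' @param compound_id optional label stored on the result.
#' @return Object of class `reactivity_descriptors`: list with fields
#'   `IP`, `EA`, `gap`, `abs_gap`, `eta`, `softness`, `chi`, `omega`.
#' @examples
#' d <- descriptors_from_ip_ea(8, 2)
#' d$eta      # 3
#' d$omega    # 25/6
#' @export
descriptors_from_ip_ea <- function(IP, EA, compound_id = NA_character_) {
  if (!is.finite(IP) || !is.finite(EA))
    stop("descriptors_from_ip_ea: IP and EA must be finite")
  eta <- (IP - EA) / 2
  chi <- (IP + EA) / 2
  if (eta == 0) {
    warning(structure(
      class = c("pocketfp_degenerate_hardness", "warning", "condition"),
      list(message = "degenerate hardness (IP == EA): softness and omega undefined",
           call = sys.call(-1))))
    softness <- NA_real_
    omega <- NA_real_
  } else {
    softness <- 1 / (2 * eta)
    omega <- chi^2 / (2 * eta)
  }
  structure(list(compound_id = compound_id,
                 IP = IP, EA = EA,
                 gap = EA - IP, abs_gap = abs(IP - EA),
                 eta = eta, softness = softness, chi = chi, omega = omega),
            class = "reactivity_descriptors")
}

#' Reactivity descriptors via the Koopmans approximation
#'
#' IP = -eps_HOMO and EA = -eps_LUMO, then delegates to
#' [descriptors_from_ip_ea()].
#'
#' @param orb a [frontier_orbitals()].
#' @return A `reactivity_descriptors` object.
#' @export
descriptors_from_orbitals <- function(orb) {
  stopifnot(inherits(orb, "frontier_orbitals"))
  descriptors_from_ip_ea(-orb$eps_homo, -orb$eps_lumo,
                         compound_id = orb$compound_id)
}

#' Full descriptor set from a species energy set
#'
#' @param species a [species_energy_set()].
#' @return A `reactivity_descriptors` object.
#' @export
descriptors_from_species <- function(species) {
  descriptors_from_ip_ea(compute_ip(species), compute_ea(species),
                         compound_id = species$compound_id)
}

#' @export
print.reactivity_descriptors <- function(x, ...) {
  cat("Reactivity descriptors",
      if (!is.na(x$compound_id)) paste0("for ", x$compound_id), "\n")
  cat(sprintf("  IP      %8.4f eV\n  EA      %8.4f eV\n", x$IP, x$EA))
  cat(sprintf("  gap     %8.4f eV (signed EA-IP; |gap| = %.4f)\n", x$gap, x$abs_gap))
  cat(sprintf("  eta     %8.4f eV\n  S       %8.4f 1/eV\n  chi     %8.4f eV\n  omega   %8.4f eV\n",
              x$eta, x$softness, x$chi, x$omega))
  invisible(x)
}

#' Compare two compounds' descriptors
#'
#' Per-field signed differences (a - b) and a donor/acceptor verdict: the
#' compound with both the larger EA and the larger omega is flagged the
#' stronger electron acceptor; if the two fields disagree the verdict is
#' `"indeterminate"`, and `"equivalent"` when all differences vanish.
#'
#' @param a,b `reactivity_descriptors` objects.
#' @return List with `diff` (named numeric vector of a - b differences)
#'   and `verdict`.
#' @export
compare_compounds <- function(a, b) {
  stopifnot(inherits(a, "reactivity_descriptors"),
            inherits(b, "reactivity_descriptors"))
  fields <- c("IP", "EA", "gap", "abs_gap", "eta", "softness", "chi", "omega")
  d <- vapply(fields, function(f) a[[f]] - b[[f]], numeric(1))
  verdict <-
    if (all(d[!is.na(d)] == 0)) "equivalent"
    else if (a$EA > b$EA && a$omega > b$omega) "a stronger acceptor"
    else if (b$EA > a$EA && b$omega > a$omega) "b stronger acceptor"
    else "indeterminate"
  list(diff = d, verdict = verdict)
}

#' Read a species-energy or frontier-orbital table
#'
#' CSV with either columns `compound_id, E_neutral, E_cation, E_anion, unit`
#' or columns `compound_id, eps_homo, eps_lumo` (eV).
#'
#' @param path CSV file path.
#' @param from_orbitals interpret the table as frontier-orbital energies.
#' @return List of `species_energy_set` or `frontier_orbitals` objects.
#' @export
read_species_table <- function(path, from_orbitals = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (from_orbitals) {
    need <- c("compound_id", "eps_homo", "eps_lumo")
    if (!all(need %in% names(tab)))
      stop("orbital table must have columns: ", paste(need, collapse = ", "))
    lapply(seq_len(nrow(tab)), function(i)
      frontier_orbitals(tab$compound_id[i], tab$eps_homo[i], tab$eps_lumo[i]))
  } else {
    need <- c("compound_id", "E_neutral", "E_cation", "E_anion", "unit")
    if (!all(need %in% names(tab)))
      stop("species table must have columns: ", paste(need, collapse = ", "))
    lapply(seq_len(nrow(tab)), function(i)
      species_energy_set(tab$compound_id[i], tab$E_neutral[i],
                         tab$E_cation[i], tab$E_anion[i], unit = tab$unit[i]))
  }
}

#' Descriptor table for a list of compounds
#'
#' @param species_list list of `species_energy_set` or `frontier_orbitals`.
#' @return data.frame, one row per compound, one column per descriptor.
#' @export
descriptor_table <- function(species_list) {
  rows <- lapply(species_list, function(s) {
    d <- if (inherits(s, "frontier_orbitals")) descriptors_from_orbitals(s)
         else descriptors_from_species(s)
    data.frame(compound_id = d$compound_id, IP = d$IP, EA = d$EA,
               gap = d$gap, abs_gap = d$abs_gap, eta = d$eta,
               softness = d$softness, chi = d$chi, omega = d$omega,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
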