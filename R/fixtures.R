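#' Packaged structure-screen fixture for the PDE3B template
#'
#' The bundled binding-site-similarity and docking tables for the PDE3B
#' off-target screen: 20 candidate structures compared against the PDE3B
#' template (PDB 1SO2), each docked with the five PDE3 inhibitors
#' (milrinone, anagrelide, levosimendan, amrinone, enoximone). Useful as a
#' small real-world input for [filter_offtarget_candidates()]: at the
#' default thresholds (p < 2e-3, score < -7.5) levosimendan retains 16
#' off-target pairs — including the RIOK1 structure 4OTP — and amrinone
#' retains one.
#'
#' @return List with data.frames `sites` (template_id, candidate_structure,
#'   protein_key, p_value) and `docks` (protein_key, chemical_key, score).
#' @examples
#' fx <- offtarget_screen_fixture()
#' hits <- filter_offtarget_candidates(fx$sites, fx$docks)
#' table(hits$chemical_key)
#' @export
offtarget_screen_fixture <- function() {
  list(sites = read_site_hits(system.file("extdata", "pde3b_site_hits.tsv",
                                          package = "winoccf",
                                          mustWork = TRUE)),
       docks = read_docking_scores(system.file("extdata", "pde3b_docking.tsv",
                                               package = "winoccf",
                                               mustWork = TRUE)))
}
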