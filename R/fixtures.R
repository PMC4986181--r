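#' Deterministic worked-example fixtures
#'
#' Small networks realizing the published worked examples of the synergy and
#' side-effect scores, plus the three canonical length-4 cycle patterns.
#' Every fixture is fully deterministic (no RNG). Drug and target
#' identifiers are descriptive but synthetic.
#'
#' Available names:
#' \describe{
#'   \item{`modafinil_pair`}{Two drugs inhibiting one shared pharmacological
#'     target, with opposite-sign actions on one shared off-target and no
#'     other edges. Both side-effect scores equal 1.}
#'   \item{`icosapent_pair`}{Two drugs agonist on one shared pharmacological
#'     target, incoherent on one shared off-target; drug A has 8 additional
#'     private off-targets. Side-effect scores 1/9 and 1.}
#'   \item{`panitumumab_pair`}{Two drugs whose only target is one shared
#'     pharmacological target, both negative. Both synergistic scores 1.}
#'   \item{`fig6a`}{One shared coherent pharmacological target; two shared
#'     off-targets, one incoherent, one coherent; drug 2 has one private
#'     off-target. Both side-effect scores 0.}
#'   \item{`fig6b`}{One shared coherent pharmacological target; one shared
#'     incoherent off-target; drugs have 2 and 4 off-targets in total.
#'     Side-effect scores 0.5 and 0.25.}
#'   \item{`fig3_cycles`}{Three disjoint 2-drug/2-target squares realizing
#'     one coherent, one mixed and one incoherent cycle pattern.}
#'   \item{`amitriptyline_pair`}{Drug A: 33 targets, 1 pharmacological;
#'     drug B: 17 targets, 5 pharmacological; 1 shared pharmacological
#'     target (both negative); 5 shared off-targets, 4 coherent and 1
#'     incoherent. Both side-effect scores negative (-3/32 and -1/4).}
#' }
#'
#' @param name One of the fixture names above.
#' @return A [signed_dtn()].
#' @export
generate_fixture <- function(name) {
  builders <- list(
    modafinil_pair = fixture_modafinil,
    icosapent_pair = fixture_icosapent,
    panitumumab_pair = fixture_panitumumab,
    fig6a = fixture_fig6a,
    fig6b = fixture_fig6b,
    fig3_cycles = fixture_fig3_cycles,
    amitriptyline_pair = fixture_amitriptyline
  )
  if (!name %in% names(builders)) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

edge_row <- function(drug, target, sign, pharm) {
  data.frame(drug = drug, target = target, sign = as.integer(sign),
             pharmacological = pharm, stringsAsFactors = FALSE)
}

fixture_modafinil <- function() {
  signed_dtn(rbind(
    edge_row("drugA", "pharm_target", -1, TRUE),   # both inhibit on-target
    edge_row("drugB", "pharm_target", -1, TRUE),
    edge_row("drugA", "off_target", +1, FALSE),    # partial agonist
    edge_row("drugB", "off_target", -1, FALSE)     # antagonist
  ))
}

fixture_icosapent <- function() {
  private <- do.call(rbind, lapply(seq_len(8), function(k) {
    edge_row("drugA", sprintf("privateA_%02d", k), -1, FALSE)
  }))
  signed_dtn(rbind(
    edge_row("drugA", "pharm_target", +1, TRUE),   # both agonists
    edge_row("drugB", "pharm_target", +1, TRUE),
    edge_row("drugA", "off_target", +1, FALSE),    # inducer
    edge_row("drugB", "off_target", -1, FALSE),    # inhibitor
    private
  ))
}

fixture_panitumumab <- function() {
  signed_dtn(rbind(
    edge_row("drugA", "pharm_target", -1, TRUE),
    edge_row("drugB", "pharm_target", -1, TRUE)
  ))
}

fixture_fig6a <- function() {
  signed_dtn(rbind(
    edge_row("drug1", "pharm_target", +1, TRUE),   # coherent on-target pair
    edge_row("drug2", "pharm_target", +1, TRUE),
    edge_row("drug1", "off_incoherent", +1, FALSE),
    edge_row("drug2", "off_incoherent", -1, FALSE),
    edge_row("drug1", "off_coherent", +1, FALSE),
    edge_row("drug2", "off_coherent", +1, FALSE),
    edge_row("drug2", "private2_01", -1, FALSE)    # drug 2's third off-target
  ))
}

fixture_fig6b <- function() {
  signed_dtn(rbind(
    edge_row("drug1", "pharm_target", +1, TRUE),
    edge_row("drug2", "pharm_target", +1, TRUE),
    edge_row("drug1", "off_incoherent", +1, FALSE),
    edge_row("drug2", "off_incoherent", -1, FALSE),
    edge_row("drug1", "private1_01", +1, FALSE),   # 2 off-targets total
    edge_row("drug2", "private2_01", -1, FALSE),   # 4 off-targets total
    edge_row("drug2", "private2_02", -1, FALSE),
    edge_row("drug2", "private2_03", -1, FALSE)
  ))
}

fixture_fig3_cycles <- function() {
  signed_dtn(rbind(
    # coherent square: same sign on both targets
    edge_row("cohD1", "cohT1", +1, FALSE), edge_row("cohD2", "cohT1", +1, FALSE),
    edge_row("cohD1", "cohT2", +1, FALSE), edge_row("cohD2", "cohT2", +1, FALSE),
    # mixed square: coherent on one target, incoherent on the other
    edge_row("mixD1", "mixT1", +1, FALSE), edge_row("mixD2", "mixT1", +1, FALSE),
    edge_row("mixD1", "mixT2", +1, FALSE), edge_row("mixD2", "mixT2", -1, FALSE),
    # incoherent square: opposite signs on both targets
    edge_row("incD1", "incT1", +1, FALSE), edge_row("incD2", "incT1", -1, FALSE),
    edge_row("incD1", "incT2", +1, FALSE), edge_row("incD2", "incT2", -1, FALSE)
  ))
}

fixture_amitriptyline <- function() {
  shared_coh <- do.call(rbind, lapply(seq_len(4), function(k) {
    rbind(edge_row("drugA", sprintf("shared_coh_%02d", k), -1, FALSE),
          edge_row("drugB", sprintf("shared_coh_%02d", k), -1, FALSE))
  }))
  privA <- do.call(rbind, lapply(seq_len(27), function(k) {
    edge_row("drugA", sprintf("privateA_%02d", k), -1, FALSE)
  }))
  privB_pharm <- do.call(rbind, lapply(seq_len(4), function(k) {
    edge_row("drugB", sprintf("privateB_pharm_%02d", k), -1, TRUE)
  }))
  privB <- do.call(rbind, lapply(seq_len(7), function(k) {
    edge_row("drugB", sprintf("privateB_%02d", k), -1, FALSE)
  }))
  signed_dtn(rbind(
    edge_row("drugA", "pharm_target", -1, TRUE),   # both antagonists
    edge_row("drugB", "pharm_target", -1, TRUE),
    edge_row("drugA", "shared_inc", -1, FALSE),    # antagonist vs agonist
    edge_row("drugB", "shared_inc", +1, FALSE),
    shared_coh, privA, privB_pharm, privB
  ))
}
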