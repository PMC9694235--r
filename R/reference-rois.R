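#' Reference 16-ROI rankings for the three AD assessment tasks
#'
#' The published accuracy-ranked lists of the 16 most discriminative AAL-90
#' regions per one-vs-rest assessment task (A-NM, N-AM, M-AN), bundled for
#' use with [roi_overlap()]. The intersection of the three lists is the
#' canonical seven-region discriminative set for AD assessment
#' (cingulum_mid_r, caudate_l, parietal_sup_l, frontal_mid_r, frontal_mid_l,
#' parietal_inf_l, postcentral_r).
#'
#' @return A tibble with columns `task`, `rank` (1..16) and `roi` (AAL-90
#'   region name).
#' @examples
#' roi_overlap(aal90_task_rois())
#' @export
aal90_task_rois <- function() {
  a_nm <- c(
    "cingulum_mid_r", "caudate_r", "caudate_l", "parietal_sup_l",
    "frontal_mid_r", "parietal_inf_l", "frontal_mid_l", "cuneus_r",
    "postcentral_r", "cuneus_l", "frontal_inf_oper_r", "frontal_inf_tri_r",
    "temporal_inf_r", "parietal_sup_r", "cingulum_mid_l",
    "frontal_sup_medial_r"
  )
  n_am <- c(
    "cingulum_mid_r", "caudate_r", "amygdala_l", "frontal_sup_orb_l",
    "caudate_l", "parietal_sup_l", "lingual_l", "parahippocampal_l",
    "frontal_mid_r", "parietal_inf_l", "thalamus_l", "frontal_inf_oper_l",
    "frontal_mid_l", "cuneus_r", "insula_l", "postcentral_r"
  )
  m_an <- c(
    "cingulum_mid_r", "postcentral_l", "caudate_l", "parietal_sup_l",
    "frontal_mid_r", "parietal_inf_l", "frontal_mid_l", "lingual_l",
    "postcentral_r", "cuneus_l", "frontal_inf_oper_r", "frontal_inf_tri_r",
    "temporal_inf_r", "parietal_sup_r", "cingulum_mid_l", "thalamus_l"
  )
  tibble::tibble(
    task = rep(c("A-NM", "N-AM", "M-AN"), each = 16),
    rank = rep(1:16, 3),
    roi = c(a_nm, n_am, m_an)
  )
}
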