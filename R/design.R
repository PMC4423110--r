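#' Build a balanced four-group cohort design
#'
#' Creates the study layout: younger/older crossed with sun-protected /
#' sun-exposed (groups Y-pro, Y-exp, O-pro, O-exp). Sun-protected samples
#' come from the inner arm; sun-exposed samples alternate between outer
#' arm and face. Sex alternates within each group so it is balanced and
#' never confounded with group.
#'
#' @param n_per_group samples per group (default 10).
#' @param tissue "epidermis" or "dermis".
#' @return a cohort design `data.frame` (see [read_sample_sheet()]),
#'   clinical grade columns initialised to NA.
#' @export
#' @examples
#' table(make_design(3)$group)
make_design <- function(n_per_group = 10, tissue = "epidermis") {
  stopifnot(n_per_group >= 1)
  grid <- expand.grid(age_group = c("younger", "older"),
                      exposure = c("protected", "exposed"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    idx <- seq_len(n_per_group)
    data.frame(
      age_group = grid$age_group[i],
      exposure = grid$exposure[i],
      body_site = if (grid$exposure[i] == "protected") "arm"
                  else rep(c("arm", "face"), length.out = n_per_group),
      sex = rep(c("F", "M"), length.out = n_per_group),
      stringsAsFactors = FALSE)
  }))
  rows$tissue <- tissue
  rows$group <- group_label(rows$age_group, rows$exposure)
  rows$sample_id <- sprintf("%s_%02d", gsub("-", "", rows$group),
                            stats::ave(seq_len(nrow(rows)), rows$group, FUN = seq_along))
  rows$griffiths_grade <- NA_integer_
  rows$helfrich_grade <- NA_integer_
  rows[, c("sample_id", "tissue", "age_group", "exposure", "body_site",
           "sex", "group", "griffiths_grade", "helfrich_grade")]
}

#' Select samples of a comparison and return an indicator
#' @keywords internal
comparison_index <- function(design, comparison) {
  stopifnot(length(comparison) == 2)
  if (!all(comparison %in% design$group))
    stop_mb(paste("groups absent from design:",
                  paste(setdiff(comparison, design$group), collapse = ", ")),
            "bad_comparison")
  sel <- which(design$group %in% comparison)
  list(sel = sel, g = as.numeric(design$group[sel] == comparison[1]))
}
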