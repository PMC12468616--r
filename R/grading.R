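as_grade <- function(g) {
  g <- as.integer(g)
  if (any(is.na(g)) || any(!g %in% 1:3))
    abort("grades must be integers in {1, 2, 3}")
  g
}

#' WHO grade from a mitotic count
#'
#' 2019 WHO classification of neuroendocrine neoplasms: fewer than 2
#' mitoses per 2 mm^2 is G1, 2-20 (inclusive) is G2, more than 20 is G3.
#'
#' @param count Mitotic count per 2 mm^2 (non-negative; vectorised).
#' @return Integer grade(s) in `{1, 2, 3}`.
#' @export
#' @examples
#' who_grade_mitotic(c(0, 2, 20, 21)) # 1 2 2 3
who_grade_mitotic <- function(count) {
  if (any(is.na(count)) || any(count < 0))
    abort("mitotic count must be non-negative")
  ifelse(count < 2, 1L, ifelse(count <= 20, 2L, 3L))
}

#' WHO grade from a Ki-67 index
#'
#' 2019 WHO classification: Ki-67 index below 3% is G1, 3-20% (inclusive)
#' is G2, above 20% is G3.
#'
#' @param index_pct Ki-67 index in percent, 0-100 (vectorised).
#' @return Integer grade(s) in `{1, 2, 3}`.
#' @export
#' @examples
#' who_grade_ki67(c(2.9, 3, 20, 25)) # 1 2 2 3
who_grade_ki67 <- function(index_pct) {
  if (any(is.na(index_pct)) || any(index_pct < 0 | index_pct > 100))
    abort("Ki-67 index must lie in [0, 100] percent")
  ifelse(index_pct < 3, 1L, ifelse(index_pct <= 20, 2L, 3L))
}

#' Combine component grades: the highest grade takes precedence
#'
#' When the mitotic-count grade and the Ki-67 grade disagree, the reported
#' grade is the higher of the two.
#'
#' @param grades Non-empty vector of grades in `{1, 2, 3}`.
#' @return The maximum grade.
#' @export
#' @examples
#' combined_grade(c(1, 3)) # 3
combined_grade <- function(grades) {
  g <- as_grade(grades)
  if (length(g) == 0) abort("no grades supplied")
  max(g)
}

#' Naive stain combination 1: learned H&E grade vs WHO Ki-67 grade
#'
#' Takes the maximum of the grade predicted by the H&E histogram classifier
#' and the WHO grade of the slide's hotspot Ki-67 index.
#'
#' @param hne_nn_grade Grade predicted from the H&E stain (vectorised).
#' @param ki67_hotspot_pct Hotspot (maximum qualifying patch) Ki-67 index
#'   in percent.
#' @return Integer grade(s).
#' @export
naive_combination_1 <- function(hne_nn_grade, ki67_hotspot_pct) {
  pmax(as_grade(hne_nn_grade), who_grade_ki67(ki67_hotspot_pct))
}

#' Naive stain combination 2: learned H&E grade vs learned Ki-67 grade
#'
#' Takes the maximum of the grades predicted by the two single-stain
#' histogram classifiers.
#'
#' @param hne_nn_grade,ki67_nn_grade Predicted grades (vectorised).
#' @return Integer grade(s).
#' @export
naive_combination_2 <- function(hne_nn_grade, ki67_nn_grade) {
  pmax(as_grade(hne_nn_grade), as_grade(ki67_nn_grade))
}

#' Patient-level grade from slide grades
#'
#' If slides of the same patient disagree, the higher grade is assigned to
#' the patient.
#'
#' @param slide_grades Non-empty vector of slide grades.
#' @return The patient grade (maximum).
#' @export
patient_grade <- function(slide_grades) combined_grade(slide_grades)

#' Grade-stratified cross-validation folds with test/validation roles
#'
#' Patients are shuffled (seeded) within each grade and dealt round-robin
#' into `k` folds, so per-fold grade proportions stay within one patient of
#' the global distribution. Within each fold, patients alternate between
#' `"test"` and `"val"` roles (each about half the fold, i.e. ~17% of the
#' cohort for k = 3), applied when that fold is held out.
#'
#' @param patients Data frame with columns `patient_id` and `grade`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the split is reproducible.
#' @return A tibble: `patient_id`, `grade`, `fold` (0-based),
#'   `heldout_role` (`"test"` or `"val"`).
#' @export
stratified_folds <- function(patients, k = 3L, seed = 1L) {
  stopifnot(all(c("patient_id", "grade") %in% names(patients)), k >= 2)
  grade <- as_grade(patients$grade)
  tab <- tabulate(grade, 3)
  short <- which(tab > 0 & tab < k)
  if (length(short))
    abort(sprintf("grade %s has fewer than %d patients; cannot stratify",
                  paste(short, collapse = ", "), k))
  with_seed_(seed, {
    out <- lapply(sort(unique(grade)), function(g) {
      ids <- patients$patient_id[grade == g]
      ids <- ids[sample.int(length(ids))]
      tibble::tibble(patient_id = ids, grade = g,
                     fold = (seq_along(ids) - 1L) %% as.integer(k),
                     heldout_role = ifelse(seq_along(ids) %% 2 == 1,
                                           "test", "val"))
    })
    dplyr::bind_rows(out)
  })
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall; the target metric for imbalanced
#' grade distributions.
#'
#' @param y_true,y_pred Equal-length grade vectors; every class present in
#'   `y_true` must be non-empty (it is, by definition).
#' @return Balanced accuracy in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(c(1, 2, 3), c(1, 2, 2)) # (1 + 1 + 0) / 3
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as_grade(y_true); y_pred <- as_grade(y_pred)
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred must have equal length")
  classes <- sort(unique(y_true))
  mean(vapply(classes, function(g)
    mean(y_pred[y_true == g] == g), numeric(1)))
}
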