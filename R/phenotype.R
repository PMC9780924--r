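#' @title Bacterial-wilt phenotype scores
#' @name phenotype
#'
#' @description
#' Wilting is scored per plant on a 0-4 scale (0 healthy, 4 more than 3/4
#' of leaves wilted or plant death). Two summaries are computed per
#' treatment: morbidity (percent of diseased plants) and the disease index
#' on a 0-100 scale.
NULL

validate_grades <- function(grades) {
  if (!length(grades)) stop("grade table must contain >= 1 plant")
  if (any(is.na(grades)) || any(grades != as.integer(grades)) ||
      any(grades < 0) || any(grades > 4)) {
    stop("grades must be integers in 0..4")
  }
  as.integer(grades)
}

#' Plant morbidity
#'
#' `100 * diseased / total`, where a plant is diseased when its grade is
#' at least 1 (grade 0 is defined healthy).
#'
#' @param grades integer vector of per-plant grades in 0..4
#' @return percent in `[0, 100]`
#' @export
morbidity <- function(grades) {
  g <- validate_grades(grades)
  100 * sum(g >= 1) / length(g)
}

#' Disease index
#'
#' `100 * sum(grade * n_plants_at_grade) / (4 * total plants)`. The
#' denominator uses the scale maximum 4 (not the observed maximum), so an
#' all-grade-4 table scores exactly 100.
#'
#' @inheritParams morbidity
#' @return index in `[0, 100]`
#' @export
disease_index <- function(grades) {
  g <- validate_grades(grades)
  100 * sum(g) / (4 * length(g))
}

#' Score a grade table by treatment and day
#'
#' @param table data.frame with columns `treatment`, `grade` and
#'   optionally `day`
#' @return data.frame with `treatment`, `day`, `n`, `morbidity`,
#'   `disease_index`
#' @export
score_grade_table <- function(table) {
  stopifnot(all(c("treatment", "grade") %in% names(table)))
  if (is.null(table$day)) table$day <- 1L
  keys <- unique(table[, c("treatment", "day")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$treatment == keys$treatment[i] & table$day == keys$day[i], ]
    data.frame(treatment = keys$treatment[i], day = keys$day[i],
               n = nrow(sub), morbidity = morbidity(sub$grade),
               disease_index = disease_index(sub$grade),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
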