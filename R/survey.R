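# Scoring arithmetic of the expert comparison study: five-point ratings
# become preference scores in -2..2 (0 = no difference between the two
# compared box-plot variants), and per-ensemble preferences are the mean
# expert score for that ensemble.

#' Convert a five-point rating to a preference score
#'
#' Ratings 1..5 map linearly to scores -2..2 by subtracting 3: 1 means a
#' strong preference for the baseline method, 3 no difference, 5 a strong
#' preference for the geometric-median method.
#'
#' @param r integer rating(s) in 1..5
#' @return integer score(s) in -2..2
#' @examples
#' ratingToScore(c(1, 3, 5))  # -2 0 2
#' @export
ratingToScore <- function(r) {
  if (any(!(r %in% 1:5))) stop("ratings must lie in 1..5")
  as.integer(r) - 3L
}

#' Construct a survey table
#'
#' @param values integer matrix, experts in rows, ensembles in columns
#' @param ensembleSizes number of curves in each assessed ensemble
#' @param entry "score" when values are already on -2..2, "rating" for raw
#'   1..5 ratings (converted with [ratingToScore()])
#' @return a \linkS4class{SurveyTable}
#' @export
surveyTable <- function(values, ensembleSizes,
                        entry = c("score", "rating")) {
  entry <- match.arg(entry)
  v <- as.matrix(values)
  if (entry == "rating") v[] <- ratingToScore(v)
  storage.mode(v) <- "integer"
  new("SurveyTable", scores = v, ensembleSizes = as.integer(ensembleSizes))
}

setMethod("show", "SurveyTable", function(object) {
  cat(sprintf("SurveyTable: %d experts x %d ensembles (sizes %s)\n",
              nrow(object@scores), ncol(object@scores),
              paste(object@ensembleSizes, collapse = ", ")))
})

#' Per-ensemble mean preference scores
#'
#' The methodological preference for an ensemble is the arithmetic mean of
#' the expert scores in its column; values are bounded in [-2, 2].
#'
#' @param table a \linkS4class{SurveyTable}
#' @return data.frame with columns ensemble, size, mean
#' @export
ensemblePreferenceMeans <- function(table) {
  if (!nrow(table@scores)) stop("empty survey table")
  data.frame(ensemble = seq_len(ncol(table@scores)),
             size = table@ensembleSizes,
             mean = unname(colMeans(table@scores)))
}

#' Read survey scores from CSV
#'
#' Expects one row per expert and one column per ensemble; a first header
#' row named \code{size_<k>} per column (or a separate \code{sizes}
#' attribute line) is not required - sizes are passed explicitly.
#'
#' @param path CSV of scores (experts x ensembles)
#' @param ensembleSizes ensemble sizes, one per column
#' @param entry "score" or "rating" (see [surveyTable()])
#' @return a \linkS4class{SurveyTable}
#' @export
readSurveyScores <- function(path, ensembleSizes, entry = "score") {
  df <- utils::read.csv(path, check.names = FALSE)
  df <- df[vapply(df, is.numeric, logical(1))]   # drop label columns
  surveyTable(as.matrix(df), ensembleSizes, entry = entry)
}

#' Bundled expert survey table
#'
#' The ten-expert, seven-ensemble preference score matrix of the published
#' comparison between band-depth curve box plots and the geometric-median
#' variant, with the assessed ensemble sizes (7, 7, 14, 8, 16, 9, 9).
#'
#' @return a \linkS4class{SurveyTable}
#' @examples
#' ensemblePreferenceMeans(exampleSurveyScores())
#' @export
exampleSurveyScores <- function() {
  path <- system.file("extdata", "expert_survey_scores.csv",
                      package = "rootbox", mustWork = TRUE)
  df <- utils::read.csv(path)
  surveyTable(as.matrix(df[, -1L]), c(7L, 7L, 14L, 8L, 16L, 9L, 9L))
}

#' Export per-ensemble means as CSV
#'
#' @param table a \linkS4class{SurveyTable}
#' @param path output CSV (columns ensemble, size, mean)
#' @return the path, invisibly
#' @export
exportPreferenceMeans <- function(table, path) {
  utils::write.csv(ensemblePreferenceMeans(table), path, row.names = FALSE)
  invisible(path)
}
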