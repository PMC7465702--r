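#' Reference per-subject result tables
#'
#' Per-subject performance tables from the original eight-patient
#' feasibility experiment this pipeline models, bundled as plain CSV. They
#' serve as fixed inputs for the aggregation and reporting arithmetic
#' (means, sample SDs, t-ratios): the raw EEG behind them was never
#' deposited, so the per-subject values themselves are data, not something
#' the package recomputes.
#'
#' Available tables:
#' \describe{
#'   \item{phase1_accuracy}{Cross-validated accuracy (%) per period (SMR /
#'     ACT / FES) and classifier (LDA / SVM / ensemble).}
#'   \item{completion_by_task}{Completion rate (%) per task (grasping,
#'     opening, keep, stop). Note: the originally printed grasping-column
#'     average (55.7) is inconsistent with its own entries (true mean
#'     60.7); [aggregate_summary()] recomputes from the entries.}
#'   \item{completion_by_iv}{Completion rate (%) per FES condition and
#'     learning type.}
#'   \item{accuracy_by_task, accuracy_by_iv}{Semi-asynchronous accuracy
#'     (%) per task / per condition.}
#'   \item{itr_by_iv}{Information transfer rate (bits/min) per condition.}
#'   \item{workload_ttest}{Workload-questionnaire estimates and standard
#'     errors feeding the t-ratio arithmetic (df = 7).}
#' }
#'
#' @param name Table name; omit to get the full named list.
#' @return A data.frame, or a named list of all tables.
#' @export
reference_tables <- function(name = NULL) {
  dir <- system.file("extdata", package = "smrfes")
  files <- c(phase1_accuracy = "phase1_accuracy.csv",
             completion_by_task = "completion_by_task.csv",
             completion_by_iv = "completion_by_iv.csv",
             accuracy_by_task = "accuracy_by_task.csv",
             accuracy_by_iv = "accuracy_by_iv.csv",
             itr_by_iv = "itr_by_iv.csv",
             workload_ttest = "workload_ttest.csv")
  load1 <- function(f) utils::read.csv(file.path(dir, f),
                                       stringsAsFactors = FALSE)
  if (is.null(name)) return(lapply(files, load1))
  if (!name %in% names(files))
    stop("reference_tables: unknown table ", name)
  load1(files[[name]])
}
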