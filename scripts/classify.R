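#!/usr/bin/env Rscript
# Classify per-voxel feature tables under patient-grouped cross-validation.
#
# Usage:
#   Rscript scripts/classify.R --features features.csv [--folds 10] [--seed 1]
#       [--classifiers all] [--k 6] --out metrics.json
#
# The features CSV needs the 10 feature columns plus patient_id and
# class_label (as written by the package's feature-table exports).

suppressPackageStartupMessages({
  library(optparse)
  library(ceusperf)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--features", type = "character"),
  make_option("--folds", type = "integer", default = 10L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--classifiers", type = "character", default = "all"),
  make_option("--k", type = "integer", default = 6L),
  make_option("--out", type = "character", default = "metrics.json")
)))
if (is.null(opts$features)) stop("--features is required")

table <- utils::read.csv(opts$features, stringsAsFactors = FALSE)
classifiers <- if (identical(opts$classifiers, "all")) "all" else
  strsplit(opts$classifiers, ",")[[1]]

selected <- mrmr_select(discretize_features(table), table$class_label, k = opts$k)
message("selected features: ", paste(selected, collapse = ", "))

labels <- tapply(table$class_label, table$patient_id, `[`, 1)
folds <- make_patient_folds(stats::setNames(as.character(labels), names(labels)),
                            opts$folds, seed = opts$seed)
cv <- evaluate_classifiers(table, folds, classifiers,
                           features = selected, seed = opts$seed)
print(cv)

jsonlite::write_json(list(selected_features = as.character(selected),
                          summary = cv$summary, per_fold = cv$per_fold),
                     opts$out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
csv_out <- sub("\\.json$", ".csv", opts$out)
export_metrics_csv(cv, csv_out)
message("wrote ", opts$out, " and ", csv_out)
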