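#!/usr/bin/env Rscript
# Code every post-barrier ROI into a numeric descriptor vector. The offline
# handcrafted backend (shape + intensity descriptors) is the default; set
# SLITFLOW_CNN_WEIGHTS to an AlexNet-format RDS weights file to use the
# pool5 transfer-learning coding instead.

suppressMessages(library(slitflow))

out_dir <- "results/analysis"
rois <- readRDS(file.path(out_dir, "rois_after.rds"))

weights <- Sys.getenv("SLITFLOW_CNN_WEIGHTS", "")
backend <- if (nzchar(weights)) {
  feature_backend("cnn", weights_file = weights)
} else {
  feature_backend("handcrafted")
}

features <- extract_features(rois, backend)
saveRDS(features, file.path(out_dir, "features.rds"))
write_feature_csv(features, file.path(out_dir, "features.csv"))

cat(sprintf("coded %d ROIs into %d '%s' descriptors\n",
            nrow(features$matrix), ncol(features$matrix),
            features$backend_name))
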