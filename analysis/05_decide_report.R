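#!/usr/bin/env Rscript
# Aggregate the per-ROI scores into video-level diagnoses under the three
# cooperative rules and report confusion matrices and efficiencies:
# majority voting and the 30%/40% unhealthy-percentage limits for the
# two-class problem, majority voting and maximum trustiness for the
# four-class problem. Also exports the per-video score profile (assigned
# class + normalised winning score vs truth).

suppressMessages(library(slitflow))

out_dir <- "results/analysis"
manifest <- read.csv("results/cohort/manifest.csv")
conditions <- setNames(manifest$condition, manifest$video_id)

report <- list()
show <- function(tag, cm) {
  cat(sprintf("\n%s (efficiency %s):\n", tag, format_efficiency(efficiency(cm))))
  print(cm)
  report[[tag]] <<- list(confusion = unclass(cm), efficiency = efficiency(cm))
}

two <- readRDS(file.path(out_dir, "loeo_two_class.rds"))
labs2 <- condition_to_label(conditions, "two_class")
names(labs2) <- names(conditions)
show("two_class_majority",
     build_confusion(decide_videos(two$predictions, "majority"), labs2, 0:1))
show("two_class_limit30",
     build_confusion(decide_videos(two$predictions, "percentage_limit",
                                   limit = 0.30), labs2, 0:1))
show("two_class_limit40",
     build_confusion(decide_videos(two$predictions, "percentage_limit",
                                   limit = 0.40), labs2, 0:1))

four <- readRDS(file.path(out_dir, "loeo_four_class.rds"))
labs4 <- condition_to_label(conditions, "four_class")
names(labs4) <- names(conditions)
show("four_class_majority",
     build_confusion(decide_videos(four$predictions, "majority"), labs4, 0:3))
dec_tr <- decide_videos(four$predictions, "max_trustiness")
show("four_class_trustiness", build_confusion(dec_tr, labs4, 0:3))

profile <- score_profile(dec_tr, labs4)
write.csv(profile, file.path(out_dir, "score_profile.csv"), row.names = FALSE)
jsonlite::write_json(report, file.path(out_dir, "decision_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("\nscore profile and decision report written to %s\n", out_dir))
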