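#!/usr/bin/env Rscript
# Individual diagnostic profiles: show that examinees with identical raw
# scores can hold different knowledge states ("homogeneous scores,
# heterogeneous cognition"), the case for attribute-level feedback.

suppressPackageStartupMessages(library(cdmpath))

prof <- utils::read.csv("results/classification.csv",
                        colClasses = c(map_state = "character"))

# pick the raw score with the most distinct knowledge states
split_states <- split(prof$map_state, prof$raw_score)
diversity <- vapply(split_states, function(s) length(unique(s)), integer(1L))
score <- as.integer(names(which.max(diversity)))
sub <- prof[prof$raw_score == score, ]
showcase <- sub[!duplicated(sub$map_state), ][seq_len(min(3, length(unique(sub$map_state)))), ]

cat("Raw score", score, "is held by", nrow(sub), "examinees across",
    length(unique(sub$map_state)), "distinct knowledge states.\n")
cat("Three examinees with this score but different cognitive profiles:\n")
print(showcase[, c("id", "map_state", "raw_score",
                   grep("^A", names(showcase), value = TRUE))],
      row.names = FALSE)

utils::write.csv(showcase, "results/same_score_different_states.csv",
                 row.names = FALSE, quote = FALSE)
cat("\nFull per-student profile table is results/classification.csv",
    "(one row per examinee: MAP state, posterior mastery per attribute,",
    "raw score) - the input for radar-style feedback charts.\n")
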