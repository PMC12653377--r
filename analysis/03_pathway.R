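#!/usr/bin/env Rscript
# Build the first-order learning-pathway network over the 17 most
# frequent MAP knowledge states and extract the dominant trajectory.

suppressPackageStartupMessages(library(cdmpath))

cls <- utils::read.csv("results/classification.csv",
                       colClasses = c(map_state = "character"))
tab <- tabulate_states(cls$map_state)
top <- top_states(tab, k = 17)

cat("Observed", nrow(tab), "unique states;",
    sprintf("top 17 cover %.2f%% of examinees (%d of %d);",
            100 * top$coverage, top$n_retained, attr(tab, "total_n")),
    top$n_excluded, "examinees across", nrow(top$excluded),
    "rare states excluded from the diagram.\n")

g <- build_graph(top$retained)
dp <- dominant_path(g)
cat("First-order transition network:", nrow(g$nodes), "states,",
    nrow(g$edges), "edges across levels",
    paste(range(g$nodes$level), collapse = "-"), "\n")
cat("Dominant learning trajectory:\n ",
    paste(dp, collapse = " -> "), "\n")

utils::write.csv(g$nodes, "results/pathway_states.csv", row.names = FALSE,
                 quote = FALSE)
pathway_to_json(g, "results/pathway.json")
pathway_to_dot(g, "results/pathway.dot", dominant = dp)
utils::write.csv(data.frame(step = seq_along(dp) - 1L, state = as.character(dp),
                            count = g$nodes$count[match(dp, g$nodes$state)]),
                 "results/dominant_path.csv", row.names = FALSE, quote = FALSE)
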