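#!/usr/bin/env Rscript
# Run the five-step image-to-network extraction on the simulated stack and
# compare the extracted network against the generator's ground truth.

library(lcntools)

in_dir <- file.path("results", "phantom")
out_dir <- file.path("results", "extracted")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

stack <- read_stack(file.path(in_dir, "stack.tif"))
meta <- jsonlite::read_json(file.path(in_dir, "metadata.json"),
                            simplifyVector = TRUE)

message("extracting network (DoG -> segment -> thin -> smooth -> graph) ...")
t0 <- Sys.time()
ex <- extract_network(stack)
message("extraction took ", format(round(Sys.time() - t0, 1)))

write_graph_files(ex$graph, file.path(out_dir, "graph"))
write.csv(lacuna_morphometry(ex$seg, ex$graph),
          file.path(out_dir, "lacunae.csv"), row.names = FALSE)

V <- prod(meta$params$domain_size_um)
truth <- meta$realized$overall
g <- ex$graph
recov <- data.frame(
  parameter = c("can_dn_um_per_um3", "nd_nr_per_um3", "mean_genuine_degree",
                "n_lacunae"),
  truth = c(truth$can_dn, truth$nd_nr, truth$mean_genuine_degree,
            meta$metadata$n_lacunae),
  extracted = c(total_length(g) / V,
                sum(g$nodes$kind %in% c("junction", "lacuna")) / V,
                mean(genuine_degrees(g)),
                nrow(ex$seg$lacunae)))
recov$relative_error <- recov$extracted / recov$truth - 1
write.csv(recov, file.path(out_dir, "recovery.csv"), row.names = FALSE)
write_manifest(file.path(out_dir, "manifest_extract.json"), "extract",
               list(defaults = "extract_network"),
               inputs = file.path(in_dir, "stack.tif"),
               outputs = file.path(out_dir, "recovery.csv"))

message("ground-truth recovery:")
print(recov, digits = 3)
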