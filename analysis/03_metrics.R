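#!/usr/bin/env Rscript
# Quantify the extracted network: subvolume maps of Can.Dn / Nd.Nr / Nd.Dg,
# their pairwise correlations, lacunar morphometry correlations (including the
# volume-vs-degree power law), smoothed parameter histograms and the
# cumulative node-degree distribution with its exponential-tail fit.

library(lcntools)

in_dir <- file.path("results", "extracted")
ph_dir <- file.path("results", "phantom")
out_dir <- file.path("results", "metrics")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

g <- read_graph_files(file.path(in_dir, "graph"))
meta <- jsonlite::read_json(file.path(ph_dir, "metadata.json"),
                            simplifyVector = TRUE)
dom <- meta$params$domain_size_um

map <- compute_subvolume_maps(g, dom)
write.csv(map, file.path(out_dir, "subvolume_map.csv"), row.names = FALSE)
valid <- map[map$valid, ]

message(sprintf("%d valid 400 um^3 subvolumes", nrow(valid)))
message(sprintf("  Can.Dn %.3f +/- %.3f um/um^3", mean(valid$can_dn),
                sd(valid$can_dn)))
message(sprintf("  Nd.Nr  %.4f +/- %.4f um^-3", mean(valid$nd_nr),
                sd(valid$nd_nr)))
message(sprintf("  Nd.Dg  %.2f +/- %.2f", mean(valid$nd_dg, na.rm = TRUE),
                sd(valid$nd_dg, na.rm = TRUE)))

# correlation plots condensed to fit tables
cor_rows <- list()
add_fit <- function(name, x, y) {
  ok <- is.finite(x) & is.finite(y)
  f <- linear_regression(x[ok], y[ok])
  cor_rows[[length(cor_rows) + 1]] <<-
    data.frame(pair = name, slope = f$slope, intercept = f$intercept,
               pearson_r = f$r, n = f$n)
}
add_fit("can_dn~nd_nr", valid$nd_nr, valid$can_dn)
add_fit("can_dn~nd_dg", valid$nd_dg, valid$can_dn)
add_fit("nd_dg~nd_nr", valid$nd_nr, valid$nd_dg)
cors <- do.call(rbind, cor_rows)
write.csv(cors, file.path(out_dir, "subvolume_correlations.csv"),
          row.names = FALSE)
message("subvolume correlations:")
print(cors, digits = 3)

# lacunar morphometry and the volume-degree power law
lac <- read.csv(file.path(in_dir, "lacunae.csv"))
lac_ok <- lac[!lac$flagged & lac$lc_dg > 0, ]
if (nrow(lac_ok) < 10) {
  message("too few lacunae in this block for a stable volume-degree fit (n = ",
          nrow(lac_ok), "); the shape-population route in scripts/acceptance.R ",
          "estimates the exponent from 1000 lacunae")
}
if (nrow(lac_ok) >= 10) {
  pw <- power_law_fit(lac_ok$lc_dg, lac_ok$lc_v_um3)
  message(sprintf(
    "lacunar volume ~ degree^%.2f (R = %.2f, n = %d lacunae)",
    pw$exponent, pw$r, pw$n))
  jsonlite::write_json(list(exponent = pw$exponent, prefactor = pw$prefactor,
                            pearson_r = pw$r, n = pw$n),
                       file.path(out_dir, "lacuna_powerlaw.json"),
                       auto_unbox = TRUE, digits = NA)
}

# distributions
hist_rows <- list()
push_hist <- function(name, values, edges) {
  h <- smoothed_histogram(values, edges, sigma_bins = 1)
  hist_rows[[length(hist_rows) + 1]] <<-
    data.frame(parameter = name, mid = h$mid, frequency = h$frequency)
}
push_hist("can_dn", valid$can_dn, seq(0, 0.5, by = 0.02))
push_hist("nd_nr", valid$nd_nr, seq(0, 0.12, by = 0.005))
push_hist("nd_dg", valid$nd_dg[is.finite(valid$nd_dg)], seq(3, 6, by = 0.25))
write.csv(do.call(rbind, hist_rows),
          file.path(out_dir, "smoothed_histograms.csv"), row.names = FALSE)

# cumulative node-degree distribution and its exponential tail
fit <- cumulative_degree_fit(g)
write.csv(data.frame(degree = fit$x, cumulative = fit$cumulative),
          file.path(out_dir, "degree_cumulative.csv"), row.names = FALSE)
message(sprintf(
  "cumulative degree tail: beta = %.2f over %d genuine nodes (%.0f%% degree 3)",
  fit$beta, fit$n_nodes, 100 * fit$cumulative[1] -
    100 * ifelse(length(fit$cumulative) > 1, fit$cumulative[2], 0)))
jsonlite::write_json(list(beta = fit$beta, n_nodes = fit$n_nodes),
                     file.path(out_dir, "degree_fit.json"),
                     auto_unbox = TRUE, digits = NA)
write_manifest(file.path(out_dir, "manifest_metrics.json"), "metrics",
               list(v_sub_um3 = 400),
               inputs = file.path(in_dir, "graph", "edges.csv"),
               outputs = file.path(out_dir, "subvolume_map.csv"))
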