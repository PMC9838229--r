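#!/usr/bin/env Rscript
# Thin command-line wrapper over the virtcog package.
#
#   Rscript scripts/virtcog.R list-experiments
#   Rscript scripts/virtcog.R run-experiment <name> [--plasticity weak|strong]
#                             [--trace out.trc]
#   Rscript scripts/virtcog.R run --circuit f.vcir --script s.yaml
#                             [--plasticity weak|strong] [--max-cycles N]
#                             [--trace out.trc]
#   Rscript scripts/virtcog.R gen-scenario <name> --out s.yaml
#   Rscript scripts/virtcog.R write-goldens <dir>
#   Rscript scripts/virtcog.R regress <dir>
#
# Exit code 0 iff all behavioral assertions (or golden comparisons) pass.

suppressPackageStartupMessages(library(virtcog))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0L) stop("no command given; see the header of this script")
cmd <- argv[[1]]
argv <- argv[-1]

flag <- function(name, default = NULL) {
  k <- which(argv == paste0("--", name))
  if (length(k) == 0L) return(default)
  argv[[k + 1L]]
}
positional <- Filter(function(a) !startsWith(a, "--"),
                     argv[!seq_along(argv) %in% (which(startsWith(argv, "--")) + 1L)])

status <- 0L
if (cmd == "list-experiments") {
  cat(list_experiments(), sep = "\n")
} else if (cmd == "run-experiment") {
  name <- positional[[1]]
  cfg <- list()
  pl <- flag("plasticity")
  if (!is.null(pl)) cfg$mode <- pl
  out <- run_experiment(name, config = cfg)
  print(out)
  tr <- flag("trace")
  if (!is.null(tr)) writeLines(format_trace(out$model), tr)
  if (!all(out$assertions$pass)) status <- 1L
} else if (cmd == "run") {
  spec <- parse_circuit(readLines(flag("circuit")))
  cfg <- list()
  pl <- flag("plasticity")
  if (!is.null(pl)) cfg$mode <- pl
  m <- compile_circuit(spec, new_model(cfg))
  sc <- load_scenario(flag("script"))
  w <- new_world(objects = sc$world$objects, screens = sc$world$screens,
                 boxes = sc$world$boxes, feedback = sc$world$feedback)
  run_scenario(m, w, sc, max_cycles = as.integer(flag("max-cycles", "60")))
  acts <- get_actions(m)
  for (k in seq_len(nrow(acts)))
    cat(sprintf("cycle %2d  %s\n", acts$cycle[[k]], acts$action[[k]]))
  tr <- flag("trace")
  if (!is.null(tr)) writeLines(format_trace(m), tr)
} else if (cmd == "gen-scenario") {
  save_scenario(make_scenario(positional[[1]]), flag("out", paste0(positional[[1]], ".yaml")))
} else if (cmd == "write-goldens") {
  write_goldens(positional[[1]])
} else if (cmd == "regress") {
  rep <- regress(positional[[1]])
  print(rep, row.names = FALSE)
  if (any(rep$status == "diff")) status <- 1L
} else {
  stop(sprintf("unknown command '%s'", cmd))
}
quit(status = status)
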