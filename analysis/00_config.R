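# Shared configuration for the analysis scripts. Everything downstream reads
# and writes plain-text tables under results/.
#
# Problem sizes: a 5-group, 60-marker map with 168 progeny over three years
# keeps every stage exact but quick; the generator scales to the full
# 12 x 130 composite-map geometry by editing these numbers.

MASTER_SEED <- 20240917

CFG <- list(
  seed = MASTER_SEED,
  map = list(n_lg = 5, markers_per_lg = 12, length_cm = 80),
  cross = list(n_progeny = 168),
  traits = list(years = c("2011", "2012", "2013"), uprights = 10),
  scan = list(step = 2.5, n_perm = 1000, percentile = 80,
              stepwise_percentile = 95),
  shape = list(template_size = 128, template_area = 3000)
)

RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

read_geno <- function(path = file.path(DATA_DIR, "genotypes.csv")) {
  g <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(g[, -1])
  rownames(m) <- g$progeny
  m
}
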