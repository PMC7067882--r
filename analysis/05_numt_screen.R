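#!/usr/bin/env Rscript
# Step 5: numt screen. Sliding 1000 bp mismatch profile of the chimeric query
# against the clean reference (windows with < 200 called bp are masked),
# followed by interval flagging at 4x the background rate.
library(mitodate)

pair <- read_alignment("scratch/sim/numt_pair.fasta")
q <- pair$seqs[pair$taxa == "query"]
r <- pair$seqs[pair$taxa == "reference"]
prof <- mismatch_scan(q, r, window = 1000L, step = 100L, min_called = 200L)
con <- file("results/numt_profile.tsv", "wb")
writeLines(c("start\tend\tcalled\tmismatches\trate\tmasked",
             sprintf("%d\t%d\t%d\t%d\t%s\t%s", prof$start, prof$end,
                     prof$called, prof$mismatches,
                     ifelse(prof$masked, "NA", sprintf("%.6f", prof$rate)),
                     prof$masked)), con)
close(con)

bg <- stats::median(prof$rate, na.rm = TRUE)
flags <- flag_numt_candidates(prof, background_rate = bg, fold_threshold = 4)
write_bed(flags, "results/numt_flags.bed", name = "query")
tru <- jsonlite::fromJSON("results/numt_truth.json")
message(sprintf("background rate %.4f; flagged %d interval(s):", bg,
                nrow(flags)))
for (i in seq_len(nrow(flags))) {
  message(sprintf("  [%d, %d) vs implanted [%d, %d)", flags$start[i],
                  flags$end[i], tru$segment[1], tru$segment[2]))
}
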