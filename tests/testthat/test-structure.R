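test_that("BED12 decoding reconstructs exons, CDS and gene grouping", {
  one <- read_bed12("chr1\t0\t300\tGA|t1\t0\t+\t50\t250\t0\t1\t300,\t0,")
  expect_equal(one$exon_starts[[1]], 0L)
  expect_equal(one$exon_ends[[1]], 300L)
  expect_equal(one$cds_start, 50L)
  expect_equal(one$cds_end, 250L)
  expect_equal(one$gene_id, "GA")

  two <- read_bed12("chr1\t1000\t2000\tGB|t1\t0\t+\t1000\t2000\t0\t2\t200,200,\t0,800,")
  expect_equal(two$exon_starts[[1]], c(1000L, 1800L))
  expect_equal(two$exon_ends[[1]], c(1200L, 2000L))

  nc <- read_bed12("chr1\t0\t300\tGC|t1\t0\t-\t100\t100\t0\t1\t300,\t0,")
  expect_true(nc$cds_start == nc$cds_end)  # non-coding convention

  expect_error(read_bed12("chr1\t0\t300\tG|t\t0\t+\t0\t300\t0\t2\t300,\t0,"),
               "blockCount")
  expect_error(read_bed12("chr1\t0\t300\tG|t\t0\t+\t0\t300\t0\t1\t200,\t0,"),
               "end at chromEnd")
  expect_error(read_bed12("chr1\t100\t300\tG|t\t0\t+\t50\t300\t0\t1\t200,\t0,"),
               "outside transcript span")
})

test_that("transcript-to-gene mapping file overrides the name dialect", {
  map <- data.frame(transcript_id = "t1", gene_id = "GENE9")
  m <- read_bed12("chr1\t0\t300\tt1\t0\t+\t0\t300\t0\t1\t300,\t0,", tx2gene = map)
  expect_equal(m$gene_id, "GENE9")
  expect_error(
    read_bed12("chr1\t0\t300\tt2\t0\t+\t0\t300\t0\t1\t300,\t0,", tx2gene = map),
    "missing from tx2gene")
})

test_that("the representative transcript is the longest, deterministically", {
  lines <- c(
    "chr1\t0\t1000\tG|a\t0\t+\t0\t1000\t0\t2\t150,150,\t0,850,",   # spliced 300
    "chr1\t0\t600\tG|b\t0\t+\t0\t600\t0\t2\t250,250,\t0,350,",     # spliced 500
    "chr2\t0\t1000\tH|a\t0\t+\t0\t1000\t0\t2\t200,200,\t0,800,",   # spliced 400, span 1000
    "chr2\t0\t2000\tH|b\t0\t+\t0\t2000\t0\t2\t200,200,\t0,1800,",  # spliced 400, span 2000
    "chr3\t0\t500\tK|only\t0\t-\t0\t500\t0\t1\t500,\t0,")
  m <- read_bed12(lines)
  rep <- select_representative(m)
  expect_equal(rep$tx_id[rep$gene_id == "G"], "G|b")     # larger spliced length
  expect_equal(rep$tx_id[rep$gene_id == "H"], "H|b")     # spliced tie -> larger span
  expect_equal(rep$tx_id[rep$gene_id == "K"], "K|only")  # single transcript
  # span mode prefers the genomically longer G transcript instead
  rep2 <- select_representative(m, longest = "span")
  expect_equal(rep2$tx_id[rep2$gene_id == "G"], "G|a")
})

test_that("structure metrics match hand-computed interval arithmetic", {
  plus <- read_bed12("chr1\t1000\t2000\tG|t\t0\t+\t1100\t1900\t0\t2\t200,200,\t0,800,")
  sm <- structure_metrics(plus)
  expect_equal(sm$genomic_len, 1000)
  expect_equal(sm$exon_total_len, 400)
  expect_equal(sm$intron_total_len, 600)
  expect_equal(sm$n_exon, 2L)
  expect_equal(sm$n_intron, 1L)
  expect_equal(sm$utr5_len, 100)
  expect_equal(sm$utr3_len, 100)
  expect_equal(sm$cds_len, 200)

  minus <- plus; minus$strand <- "-"
  smm <- structure_metrics(minus)
  expect_equal(smm$utr5_len, 100)  # symmetric model: the swap is invisible
  expect_equal(smm$utr3_len, 100)
  expect_equal(smm[, c("genomic_len", "exon_total_len", "cds_len")],
               sm[, c("genomic_len", "exon_total_len", "cds_len")])

  # degenerate: single-exon, fully coding
  full <- read_bed12("chr1\t0\t300\tG|t\t0\t+\t0\t300\t0\t1\t300,\t0,")
  smf <- structure_metrics(full)
  expect_equal(smf$utr5_len, 0)
  expect_equal(smf$utr3_len, 0)
  expect_equal(smf$intron_total_len, 0)
  expect_equal(smf$cds_len, 300)

  # asymmetric UTRs swap on the minus strand
  asym <- read_bed12("chr1\t0\t1000\tG|t\t0\t+\t100\t700\t0\t1\t1000,\t0,")
  asym_m <- asym; asym_m$strand <- "-"
  expect_equal(structure_metrics(asym)$utr5_len, 100)
  expect_equal(structure_metrics(asym)$utr3_len, 300)
  expect_equal(structure_metrics(asym_m)$utr5_len, 300)
  expect_equal(structure_metrics(asym_m)$utr3_len, 100)

  # spliced UTR mode counts exonic bases only
  sp <- read_bed12("chr1\t0\t2000\tG|t\t0\t+\t900\t1950\t0\t2\t500,500,\t0,1500,")
  expect_equal(structure_metrics(sp)$utr5_len, 900)            # genomic difference
  expect_equal(structure_metrics(sp, utr_mode = "spliced")$utr5_len, 500)
})

test_that("non-coding transcripts get missing CDS/UTR but full lengths", {
  nc <- read_bed12("chr1\t0\t900\tG|t\t0\t+\t400\t400\t0\t2\t300,300,\t0,600,")
  sm <- structure_metrics(nc)
  expect_true(is.na(sm$cds_len) && is.na(sm$utr5_len) && is.na(sm$utr3_len))
  expect_equal(sm$genomic_len, 900)
  expect_equal(sm$exon_total_len, 600)
})

test_that("length conservation and strand-flip swap hold on random models", {
  set.seed(123)
  for (i in 1:300) {
    t1 <- random_transcript()
    sm <- structure_metrics(t1)
    expect_equal(sm$genomic_len, sm$exon_total_len + sm$intron_total_len)
    expect_equal(sm$n_intron, sm$n_exon - 1L)
    expect_true(sm$intron_total_len == 0 || sm$n_exon > 1L)
    expect_lte(sm$utr5_len + sm$utr3_len, sm$genomic_len)
    expect_lte(sm$cds_len, sm$exon_total_len)
    sm2 <- structure_metrics(reflect_transcript(t1))
    expect_equal(sm2$utr5_len, sm$utr5_len)
    expect_equal(sm2$utr3_len, sm$utr3_len)
    expect_equal(sm2$genomic_len, sm$genomic_len)
    expect_equal(sm2$cds_len, sm$cds_len)
    expect_equal(sm2$exon_total_len, sm$exon_total_len)
  }
})

test_that("BED12 decoding agrees with rtracklayer on a written fixture", {
  set.seed(77)
  models <- do.call(rbind, lapply(1:20, function(i)
    random_transcript(gene_id = sprintf("G%02d", i))))
  path <- tempfile(fileext = ".bed")
  writeLines(promdiver:::.bed12_lines(models), path)
  mine <- read_bed12(path)
  gr <- rtracklayer::import(path, format = "BED")
  expect_equal(mine$tx_start, BiocGenerics::start(gr) - 1L)
  expect_equal(mine$tx_end, BiocGenerics::end(gr))
  blocks <- rtracklayer::blocks(gr)
  for (i in seq_along(gr)) {
    expect_equal(mine$exon_starts[[i]],
                 BiocGenerics::start(blocks[[i]]) - 1L)
    expect_equal(mine$exon_ends[[i]], BiocGenerics::end(blocks[[i]]))
  }
  expect_equal(mine$cds_start, BiocGenerics::start(gr$thick) - 1L)
  expect_equal(mine$cds_end, BiocGenerics::end(gr$thick))
})
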