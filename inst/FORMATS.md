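# Canonical detector output dialects

The four supported back-splice detectors emit tool-specific tabular files.
This note fixes one canonical dialect per tool; the package's parsers and the
fixture writers implement these definitions bit-exactly. Real-tool drift
across versions is handled by editing this note and the dialect offset spec
(`default_dialects()`), never by guessing in code.

All files are tab-separated. Strand is `+`, `-` or `.` (unknown). Blank lines
are ignored. Any other deviation from the column contract below is a parse
error naming the line number (or a warning under `lenient = TRUE`).

## ciri

1-based inclusive coordinates. One header line starting with `circRNA_ID`.

| # | column          | content                              |
|---|-----------------|--------------------------------------|
| 1 | circRNA_ID      | `chr:start|end` (informational)      |
| 2 | chr             | chromosome                           |
| 3 | circRNA_start   | back-splice acceptor, 1-based        |
| 4 | circRNA_end     | back-splice donor, 1-based inclusive |
| 5 | junction_reads  | back-splice-spanning read count      |
| 6 | strand          | `+` / `-` / `.`                      |

## findcirc

BED-like sites file, 0-based half-open, no header.

| # | column  | content                  |
|---|---------|--------------------------|
| 1 | chrom   | chromosome               |
| 2 | start   | 0-based start            |
| 3 | end     | half-open end            |
| 4 | name    | site label (ignored)     |
| 5 | n_reads | back-splice read count   |
| 6 | strand  | `+` / `-` / `.`          |

## circexplorer

BED12-derived, 0-based half-open, no header, 13 columns: the six BED fields
(`chrom start end name score strand`), then `thickStart thickEnd itemRgb
exonCount exonSizes exonOffsets`, then column 13 `readNumber` carrying the
back-splice read count. Only columns 1–3, 6 and 13 are interpreted.

## testrealign

Splice-event table (segemehl-style), 0-based half-open, no header.

| # | column  | content                                   |
|---|---------|-------------------------------------------|
| 1 | chrom   | chromosome                                |
| 2 | start   | 0-based start                             |
| 3 | end     | half-open end                             |
| 4 | type    | `C` = circular (back-splice), `N` = linear |
| 5 | n_reads | supporting read count                     |
| 6 | strand  | `+` / `-` / `.`                           |

Rows with type `N` are linear splice events and are skipped (they are not
back-splices, hence not parse errors). Whether a given testrealign version
needs a coordinate shift relative to the other tools is configured through
the per-method offsets in `default_dialects()`, not hard-coded.

## Coordinate conversion

Internal convention is 0-based half-open throughout the package. Per-method
`start_offset`/`end_offset` are added to native coordinates on harmonization:
ciri uses (-1, 0); the three 0-based dialects use (0, 0). Feature length is
preserved: internal `end - start` equals GTF/ciri `end - start + 1`.
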