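# Data note: table1.csv

`table1.csv` is a transcription of the published table of 105 evaluated CBD-based
products (product, manufacturer, normative group, product type, preliminary and final
labeling-quality score), in the printed descending-by-final-score order. It is shipped
exactly as printed, including the Mevatyl spray row (the only definitively registered
cannabis-based product in Brazil). Known internal inconsistencies of the printed table
are documented here rather than "corrected":

1. **Normative group counts.** The table contains 15 rows labelled N327. The published
   N327 group summary (median 53.50, P25 41.75) is only arithmetically consistent with
   16 N327 products, so one row's normative label is likely misprinted. The transcription
   keeps the printed labels; group-stratified medians should therefore not be treated as
   reproducible. The overall N327-vs-N660 comparison (p < 0.001) is robust to either
   labelling.
2. **Not-very-satisfactory class median.** The published class median is 16.0, but the
   order-statistic median of the 39 printed final scores in that band is 17.
3. **Very-satisfactory class IQR.** The published IQR 12.0-19.0 is impossible for a band
   whose scores are all >= 50; it is likely a transposition from another band. Published
   class IQRs are not reproducible from the printed rows.

Scores are total points over a 45-criterion weighted rubric; final >= preliminary for
every row (an e-mail follow-up could only add information). Five rows have
final > preliminary: CBfarma (52->68), USAHemp CBD full spectrum (41->62),
Epixann 10% (29->46), Enecta CBD (32->43), CBDAlchemy Oil (26->36).
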