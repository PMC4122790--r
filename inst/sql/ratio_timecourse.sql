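-- Per-frame mean and standard deviation, over cells, of the
-- background-corrected numerator/denominator fluorescence ratio.
-- Cells with a non-positive denominator are excluded from that frame.
SELECT m1.frame AS frame,
       AVG(m1.value / m2.value) AS mean_ratio,
       CASE WHEN COUNT(*) > 1 THEN
         sqrt(max(0.0,
           (SUM((m1.value / m2.value) * (m1.value / m2.value))
            - SUM(m1.value / m2.value) * SUM(m1.value / m2.value) / COUNT(*))
           / (COUNT(*) - 1)))
       ELSE 0.0 END AS sd_ratio,
       COUNT(*) AS n
FROM measurement m1
JOIN measurement m2
  ON m1.cell = m2.cell AND m1.frame = m2.frame
WHERE m1.channel = :num AND m1.variable = 'mean_corrected'
  AND m2.channel = :den AND m2.variable = 'mean_corrected'
  AND m2.value > 0
GROUP BY m1.frame
ORDER BY m1.frame
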