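source	target	sign	neto	context	evidence
Bud6	For3	+	FALSE	pair_example	unidirectional pair: Bud6 promotes polar recruitment of For3
For3	Bud6	-	FALSE	pair_example	unidirectional pair: For3 prevents excess accumulation of Bud6
Tip1	Tea1	+	FALSE	pair_example	unidirectional pair: Tip1 promotes polar recruitment of Tea1
Tea1	Tip1	-	FALSE	pair_example	unidirectional pair: Tea1 prevents excess accumulation of Tip1
For3	Myo52	+	FALSE	pair_example	unidirectional pair: For3 promotes polar recruitment of Myo52
Myo52	For3	-	FALSE	pair_example	unidirectional pair: Myo52 prevents excess accumulation of For3
Tea3	Tea1	+	FALSE	pair_example	unidirectional pair: Tea3 promotes polar recruitment of Tea1
Tea1	Tea3	-	FALSE	pair_example	unidirectional pair: Tea1 prevents excess accumulation of Tea3
Mod5	Tea3	+	FALSE	pair_example	unidirectional pair: Mod5 promotes polar recruitment of Tea3
Tea3	Mod5	-	FALSE	pair_example	unidirectional pair: Tea3 prevents excess accumulation of Mod5
Tea1	Tea4	+	FALSE	pair_example	positive amplification pair: Tea1 and Tea4 promote each other
Tea4	Tea1	+	FALSE	pair_example	positive amplification pair: Tea1 and Tea4 promote each other
Tea1	Tea2	+	TRUE	pair_example	positive amplification pair: Tea1 and Tea2 promote each other; Tea1 loss also shifts the two-end distribution of Tea2
Tea2	Tea1	+	FALSE	pair_example	positive amplification pair: Tea1 and Tea2 promote each other
Tea1	Mod5	+	FALSE	pair_example	positive amplification pair: Tea1 and Mod5 promote each other
Mod5	Tea1	+	FALSE	pair_example	positive amplification pair: Tea1 and Mod5 promote each other
Bud6	Myo52	+	FALSE	pair_example	positive amplification pair: Bud6 and Myo52 promote each other
Myo52	Bud6	+	FALSE	pair_example	positive amplification pair: Bud6 and Myo52 promote each other
Myo52	Tea2	-	FALSE	pair_example	negative reduction pair: Myo52 and Tea2 inhibit each other
Tea2	Myo52	-	FALSE	pair_example	negative reduction pair: Myo52 and Tea2 inhibit each other
Tea1	Bud6	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Bud6	For3	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
For3	Myo52	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Myo52	Tea1	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
For3	Tip1	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Tip1	Tea1	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Tea1	Tea2	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Tea2	Mod5	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Mod5	Tea1	+	FALSE	positive_loop	edge of the all-positive loops through Tea1
Myo52	For3	-	FALSE	negative_loop	edge of the five-protein negative feedback loop
For3	Bud6	-	FALSE	negative_loop	edge of the five-protein negative feedback loop
Bud6	Tea3	+	FALSE	negative_loop	edge of the five-protein negative feedback loop; sign inferred from the loop's overall negative sign
Tea3	Tea2	+	FALSE	negative_loop	edge of the five-protein negative feedback loop; sign inferred from the loop's overall negative sign
Tea2	Myo52	-	FALSE	negative_loop	edge of the five-protein negative feedback loop
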