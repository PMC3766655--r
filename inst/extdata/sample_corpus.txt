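The ward was quiet that morning; the monitors hummed, and the charge nurse
walked the corridor with a clipboard under one arm. "Check the vent in bed
four," she said — the same words she had said a hundred times before. The
resident checked the vent in bed four. The pressure was high, the saturation
was low, and the resident turned the oxygen up a notch, then turned the rate
down, then waited. Waiting is most of the work; the rest of the work is
turning small dials in small steps and watching what the numbers do.

Don't mistake habit for laziness. A habit is a solution that worked, kept
close at hand because it worked, and reached for first because it is close.
The ward's language is built of such habits: the common phrases spoken many
times a day, the rare phrases spoken once a season. Count the phrases and
rank them, and the counts fall away from the top rank in a long, smooth
slide — the common ones very common, the rare ones very rare, with no sharp
edge anywhere between them.

The night shift tells the same story with different nouns: a drip instead of
a dial, a lab value instead of a pressure. The grammar, though — the grammar
is the same.
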