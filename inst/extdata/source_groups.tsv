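source	group	state
Lean beef	lean_meat	raw
Lean pork	lean_meat	raw
Lean goat meat	lean_meat	raw
Lean rabbit meat	lean_meat	raw
Beef meat fat	meat_fat	raw
Rabbit meat fat	meat_fat	raw
Sheep meat fat	meat_fat	raw
Buffalo meat fat	meat_fat	raw
Beef heart	meat_offal	raw
Beef liver	meat_offal	raw
Rabbit liver	meat_offal	raw
Beef rumen and intestines	meat_offal	raw
Bovine colostrum	dairy	raw
Cow milk	dairy	raw
Buffalo milk	dairy	raw
Goat milk	dairy	raw
Sheep milk	dairy	raw
Camel milk	dairy	raw
Tilapia fish	seafood	raw
Pearl oyster	seafood	raw
Sea cucumber	seafood	raw
Cooked lean beef	lean_meat	processed
Cooked lean pork	lean_meat	processed
Cooked pork fat	meat_fat	processed
Cooked beef heart	meat_offal	processed
Cooked pork liver	meat_offal	processed
Ultrasonicated milk	dairy	processed
Skimmed powder milk	dairy	processed
Butter	dairy	processed
Infant formula	dairy	processed
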