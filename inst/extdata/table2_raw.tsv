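mirna	sources
let-7a-5p	Lean pork; Beef meat fat; Rabbit meat fat; Bovine colostrum; Cow milk; Buffalo milk; Goat milk; Sheep milk; Camel milk; Pearl oyster
let-7b-5p	Beef meat fat; Bovine colostrum; Cow milk; Buffalo milk; Goat milk; Sheep milk; Camel milk
let-7c-5p	Beef meat fat; Buffalo meat fat; Camel milk
let-7d-5p	Lean rabbit meat
let-7f-5p	Lean pork; Beef meat fat; Buffalo meat fat; Beef liver; Bovine colostrum; Goat milk; Camel milk
let-7i-5p	Rabbit meat fat
miR-1-3p	Tilapia fish; Lean beef; Lean pork; Lean rabbit meat; Sheep meat fat; Beef heart
miR-100-5p	Beef heart; Beef rumen and intestines; Rabbit liver; Pearl oyster
miR-101-3p	Lean rabbit meat
miR-10a-5p	Lean beef; Beef rumen and intestines
miR-10b-5p	Lean beef; Lean goat meat; Lean pork; Beef heart; Beef rumen and intestines
miR-122-5p	Beef liver; Rabbit liver
miR-125b-5p	Beef meat fat; Sheep meat fat; Tilapia fish; Pearl oyster; Sea cucumber
miR-126-3p	Beef meat fat
miR-133a-3p	Lean pork; Lean rabbit meat; Sheep meat fat; Tilapia fish
miR-141-3p	Lean beef; Cow milk; Buffalo milk; Goat milk
miR-143-3p	Lean beef; Lean goat meat; Lean pork; Rabbit meat fat; Buffalo meat fat; Beef heart; Beef liver; Beef rumen and intestines
miR-145-5p	Beef rumen and intestines
miR-148a-3p	Lean beef; Lean goat meat; Beef liver; Rabbit liver; Bovine colostrum; Cow milk; Buffalo milk; Goat milk; Sheep milk
miR-17-5p	Tilapia fish
miR-181a-5p	Lean goat meat; Buffalo meat fat; Bovine colostrum
miR-184	Pearl oyster; Sea cucumber
miR-191-5p	Lean goat meat; Camel milk
miR-192-5p	Beef liver; Beef rumen and intestines
miR-199a-3p	Beef meat fat; Tilapia fish
miR-200a-3p	Buffalo milk; Goat milk; Sheep milk
miR-200c-3p	Cow milk; Camel milk
miR-206	Lean beef; Lean pork; Lean rabbit meat; Sheep meat fat; Tilapia fish
miR-21-5p	Lean beef; Lean goat meat; Beef rumen and intestines; Bovine colostrum; Cow milk; Buffalo milk; Goat milk; Sheep milk
miR-22-3p	Lean beef; Lean goat meat; Beef liver; Bovine colostrum; Cow milk; Tilapia fish
miR-223-3p	Goat milk
miR-24-3p	Beef rumen and intestines
miR-25-3p	Buffalo milk; Camel milk
miR-26a-5p	Lean beef; Lean goat meat; Lean pork; Rabbit meat fat; Sheep meat fat; Buffalo meat fat; Beef heart; Beef liver; Beef rumen and intestines; Bovine colostrum; Cow milk; Goat milk; Sheep milk; Pearl oyster
miR-26b-5p	Lean rabbit meat; Sheep milk
miR-27b-3p	Lean beef; Lean rabbit meat; Buffalo meat fat; Beef liver; Beef rumen and intestines; Pearl oyster
miR-29a-3p	Sheep milk
miR-29b-3p	Camel milk
miR-30a-5p	Lean beef; Lean goat meat; Beef heart; Beef liver; Beef rumen and intestines; Bovine colostrum; Cow milk; Goat milk; Sheep milk
miR-30c-5p	Sheep meat fat
miR-30d-5p	Sheep meat fat; Cow milk
miR-30e-5p	Beef heart; Pearl oyster
miR-451a	Buffalo meat fat
miR-92a-3p	Camel milk; Sea cucumber
miR-92b-3p	Sea cucumber
miR-99a-5p	Rabbit meat fat; Beef heart; Rabbit liver; Pearl oyster
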